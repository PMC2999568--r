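## Seeded generator for four-class HMG-like domain families with ground
## truth: true tree, true ancestral sequences, class truncations, optional
## HMGB insert, and a planted downstream motif in the alpha1 classes.

#' Simulation configuration
#'
#' Desk-scale defaults emulate the study conditions: four domain classes on
#' a common-ancestor tree (alpha1 nested inside a paraphyletic MATA_HMG,
#' SOX and HMGB successively more distant), an LG+G substitution process, a
#' 40-residue conserved core, class truncations of 2 (alpha1-a) and 4
#' (alpha1-b) residues, and a 7-position motif planted 0-60 residues
#' downstream of the domain in the alpha1 sequences only.
#'
#' @param seed RNG seed (mandatory).
#' @param n_per_class sequences per class: named vector with entries
#'   `ALPHA1_A`, `ALPHA1_B`, `MATA_HMG`, `SOX`, `HMGB` (default 6/6/12/12/12,
#'   i.e. 12 alpha1 of 48 total, the classes in the study's ratio of roles
#'   rather than its raw counts).
#' @param core_length conserved-core length (default 40).
#' @param alpha gamma shape of the generating LG+G model (default 0.8).
#' @param k gamma categories (default 4).
#' @param intra_depth within-class coalescent depth in expected
#'   substitutions per site (default 0.15, the tight within-class clusters
#'   of the study system; alpha1 subclades use half).
#' @param stem_deep,stem_mid,stem_in inter-class stem lengths: HMGB split,
#'   SOX split, and the splits inside the MATA_HMG group (defaults 0.4,
#'   0.3, 0.15).
#' @param alpha1_stem length of the edge subtending the alpha1 clade
#'   (default 0.4, set so the clade is decisively supported, as in the
#'   study system).
#' @param truncation named residue counts removed from the core C-terminus
#'   (default `c(ALPHA1_A = 2, ALPHA1_B = 4)`).
#' @param motif_pattern PROSITE pattern planted downstream of the domain
#'   (default `"Y-[LMIF]-x(3)-G-[WL]"`).
#' @param motif_classes classes that receive a planted instance (default
#'   the two alpha1 subclades).
#' @param motif_window downstream window within which the instance starts
#'   (default 60).
#' @param n_flank,c_flank flanking lengths for full proteins (defaults 10
#'   and 80).
#' @param hmgb_insert `NULL`, or `list(length =, fraction =)` giving the
#'   minority insert block placed mid-core in a fraction of HMGB rows
#'   (default 5 residues in 25% of rows).
#' @return a `"simulation_config"` list.
#' @export
simulation_config <- function(seed,
                              n_per_class = c(ALPHA1_A = 6, ALPHA1_B = 6,
                                              MATA_HMG = 12, SOX = 12,
                                              HMGB = 12),
                              core_length = 40, alpha = 0.8, k = 4,
                              intra_depth = 0.15, stem_deep = 0.4,
                              stem_mid = 0.3, stem_in = 0.15,
                              alpha1_stem = 0.4,
                              truncation = c(ALPHA1_A = 2, ALPHA1_B = 4),
                              motif_pattern = "Y-[LMIF]-x(3)-G-[WL]",
                              motif_classes = c("ALPHA1_A", "ALPHA1_B"),
                              motif_window = 60, n_flank = 10, c_flank = 80,
                              hmgb_insert = list(length = 5, fraction = 0.25)) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (core_length <= 0 || n_flank < 0 || c_flank <= 0)
    stop("lengths must be positive", call. = FALSE)
  if (any(truncation >= core_length))
    stop("truncations must be smaller than the core length", call. = FALSE)
  cfg <- list(seed = as.integer(seed), n_per_class = n_per_class,
              core_length = core_length, alpha = alpha, k = k,
              intra_depth = intra_depth, stem_deep = stem_deep,
              stem_mid = stem_mid, stem_in = stem_in,
              alpha1_stem = alpha1_stem, truncation = truncation,
              motif_pattern = motif_pattern, motif_classes = motif_classes,
              motif_window = motif_window, n_flank = n_flank,
              c_flank = c_flank, hmgb_insert = hmgb_insert)
  class(cfg) <- "simulation_config"
  cfg
}

#' Draw a root sequence
#'
#' I.i.d. residues from the given frequencies (default: LG stationary
#' frequencies).
#'
#' @param length sequence length (0 gives an empty string).
#' @param freqs 20 residue frequencies in PAML order.
#' @param seed RNG seed.
#' @return residue string.
#' @export
sample_root <- function(length, freqs = LG_FREQS, seed = 1) {
  if (length == 0) return("")
  with_seed(seed,
            paste(sample(AA, length, replace = TRUE, prob = freqs),
                  collapse = ""))
}

#' Simulate sequence evolution along a tree
#'
#' Each site draws one gamma-rate category at the root (site-homogeneous
#' across branches, matching the inference model); along each branch the
#' child state is drawn from `P(t * rate)`. All internal-node sequences are
#' recorded as ground truth.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param root_seq residue string at the root.
#' @param model a [rate_model()].
#' @param seed RNG seed.
#' @return list: `tips` (named residue strings), `internal` (named by node
#'   number, including the root), `site_categories`.
#' @export
evolve_on_tree <- function(tree, root_seq, model, seed = 1) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  nsites <- nchar(root_seq)
  root <- ntip + 1L
  with_seed(seed, {
    cats <- sample.int(length(model$rates), nsites, replace = TRUE)
    states <- matrix(NA_integer_, nnode, nsites)
    states[root, ] <- match(strsplit(root_seq, "")[[1]], AA)
    for (e in rev(seq_len(nrow(phy$edge)))) {  # preorder: parents first
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]; t <- phy$edge.length[e]
      for (c in unique(cats)) {
        P <- transition_probabilities(model, t, model$rates[c])
        sel <- which(cats == c)
        states[ch, sel] <- vapply(sel, function(s)
          sample.int(20L, 1L, prob = P[states[p, s], ]), 0L)
      }
    }
    tostr <- function(i) paste(AA[states[i, ]], collapse = "")
    tips <- vapply(seq_len(ntip), tostr, "")
    names(tips) <- phy$tip.label
    internal <- vapply((ntip + 1L):nnode, tostr, "")
    names(internal) <- as.character((ntip + 1L):nnode)
    list(tips = tips, internal = internal, site_categories = cats)
  })
}

#' Apply class-specific terminal truncations
#'
#' Removes the configured number of residues from one end of each sequence
#' of the designated classes (the alpha1 cores are 2 and 4 residues shorter
#' than the MATA_HMG core in the two subclades).
#'
#' @param seqs domain sequence data frame.
#' @param spec named integer vector, class -> residues removed.
#' @param end `"C"` (default) or `"N"`.
#' @return the truncated data frame.
#' @export
apply_class_truncation <- function(seqs, spec = c(ALPHA1_A = 2, ALPHA1_B = 4),
                                   end = c("C", "N")) {
  end <- match.arg(end)
  if (length(spec) == 0) return(seqs)
  for (cls in names(spec)) {
    i <- seqs$class == cls
    n <- spec[[cls]]
    if (any(nchar(seqs$seq[i]) <= n))
      stop("truncation not smaller than sequence length", call. = FALSE)
    seqs$seq[i] <- if (end == "C")
      substr(seqs$seq[i], 1L, nchar(seqs$seq[i]) - n)
    else substr(seqs$seq[i], n + 1L, nchar(seqs$seq[i]))
  }
  seqs
}

sample_pattern_instance <- function(pattern, freqs = rep(1 / 20, 20)) {
  paste(vapply(pattern$elements, function(e) {
    span <- if (e$min == e$max) e$min else sample(e$min:e$max, 1L)
    pool <- switch(e$type,
                   literal = e$residues,
                   set = e$residues,
                   wildcard = AA,
                   negated = setdiff(AA, e$residues))
    pr <- if (e$type %in% c("wildcard", "negated"))
      setNames(freqs, AA)[pool] else NULL
    paste(sample(pool, span, replace = TRUE, prob = pr), collapse = "")
  }, ""), collapse = "")
}

#' Embed domain cores in full-length proteins with a planted motif
#'
#' Random flanks are drawn from the LG stationary frequencies; for the
#' designated classes one instance sampled uniformly from the pattern's
#' language is written into the downstream window at a recorded offset.
#'
#' @param cores domain sequence data frame of core sequences.
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @return list: `proteins` (domain sequence data frame), `domain_end`
#'   (named vector), `motif` (data frame id/start/instance, planted motifs
#'   only).
#' @export
build_full_proteins <- function(cores, config, seed = 1) {
  pat <- parse_pattern(config$motif_pattern)
  if (config$c_flank < pat$min_length)
    stop("flank shorter than the motif", call. = FALSE)
  with_seed(seed, {
    n <- nrow(cores)
    nf <- config$n_flank; cf <- config$c_flank
    prot <- character(n); dend <- integer(n)
    motif <- list()
    for (i in seq_len(n)) {
      left <- paste(sample(AA, nf, replace = TRUE, prob = LG_FREQS),
                    collapse = "")
      right <- paste(sample(AA, cf, replace = TRUE, prob = LG_FREQS),
                     collapse = "")
      full <- paste0(left, cores$seq[i], right)
      dend[i] <- nf + nchar(cores$seq[i])
      if (cores$class[i] %in% config$motif_classes) {
        inst <- sample_pattern_instance(pat)
        maxoff <- min(config$motif_window, cf) - nchar(inst)
        off <- sample.int(maxoff + 1L, 1L) - 1L
        start <- dend[i] + 1L + off
        substr(full, start, start + nchar(inst) - 1L) <- inst
        motif[[length(motif) + 1L]] <-
          data.frame(id = cores$id[i], start = start, instance = inst)
      }
      prot[i] <- full
    }
    proteins <- domain_sequences(cores$id, prot, class = cores$class,
                                 taxon = cores$taxon)
    list(proteins = proteins, domain_end = setNames(dend, cores$id),
         motif = if (length(motif)) do.call(rbind, motif)
                 else data.frame(id = character(0), start = integer(0),
                                 instance = character(0)))
  })
}

subtree_newick <- function(n, depth, prefix, seed) {
  labels <- sprintf("%s_%02d", prefix, seq_len(n))
  if (n == 1L) return(list(nwk = labels, labels = labels))
  tr <- with_seed(seed, ape::rcoal(n, tip.label = labels))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * depth
  nwk <- ape::write.tree(tr)
  list(nwk = sub(";$", "", nwk), labels = labels)
}

#' Generate the full four-class dataset with ground truth
#'
#' Builds the true rooted tree (alpha1 clade attached inside the MATA_HMG
#' subtree; SOX and HMGB successively more distant), evolves a core under
#' LG+G, applies class truncations and the optional HMGB minority insert,
#' embeds cores in full proteins with the planted motif, and records all
#' ground truth.
#'
#' @param config a [simulation_config()].
#' @return list of class `"hmg_dataset"`: `core_sequences`,
#'   `core_alignment` (truncations and inserts padded with gaps),
#'   `proteins`, `domain_end`, `tree` (true rooted `phylo`),
#'   `true_ancestors` (named internal-node residue strings),
#'   `motif` (planted positions), `config`.
#' @export
make_hmg_family_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  npc <- config$n_per_class
  seed <- config$seed
  model <- rate_model("LG+G", alpha = config$alpha, k = config$k)

  a1a <- subtree_newick(npc[["ALPHA1_A"]], config$intra_depth / 2, "A1a", seed + 1L)
  a1b <- subtree_newick(npc[["ALPHA1_B"]], config$intra_depth / 2, "A1b", seed + 2L)
  nm <- npc[["MATA_HMG"]]
  m1 <- subtree_newick(ceiling(nm / 2), config$intra_depth, "MatA", seed + 3L)
  m2 <- subtree_newick(floor(nm / 2), config$intra_depth, "MatB", seed + 4L)
  sox <- subtree_newick(npc[["SOX"]], config$intra_depth, "Sox", seed + 5L)
  hmgb <- subtree_newick(npc[["HMGB"]], config$intra_depth, "Hmgb", seed + 6L)

  half <- config$alpha1_stem / 2
  nwk <- sprintf(
    "(%s:%g,(%s:%g,(%s:%g,(%s:%g,(%s:%g,%s:%g):%g):%g):%g):%g);",
    hmgb$nwk, config$stem_deep,
    sox$nwk, config$stem_mid,
    m1$nwk, config$stem_in,
    m2$nwk, config$stem_in,
    a1a$nwk, half, a1b$nwk, half, config$alpha1_stem,
    config$stem_in, config$stem_mid, config$stem_deep)
  tree <- ape::read.tree(text = nwk)

  root_seq <- sample_root(config$core_length, LG_FREQS, seed + 7L)
  ev <- evolve_on_tree(tree, root_seq, model, seed = seed + 8L)

  classes <- c(setNames(rep("ALPHA1_A", length(a1a$labels)), a1a$labels),
               setNames(rep("ALPHA1_B", length(a1b$labels)), a1b$labels),
               setNames(rep("MATA_HMG", length(m1$labels)), m1$labels),
               setNames(rep("MATA_HMG", length(m2$labels)), m2$labels),
               setNames(rep("SOX", length(sox$labels)), sox$labels),
               setNames(rep("HMGB", length(hmgb$labels)), hmgb$labels))
  ids <- names(ev$tips)
  cores <- domain_sequences(ids, ev$tips, class = classes[ids])
  cores <- apply_class_truncation(cores, config$truncation)

  # gap-padded core alignment: truncated tails become gaps
  aligned <- vapply(seq_len(nrow(cores)), function(i) {
    s <- cores$seq[i]
    paste0(s, strrep("-", config$core_length - nchar(s)))
  }, "")

  # HMGB minority insert: extra residues mid-core in a fraction of rows,
  # producing gap columns everywhere else
  ins <- config$hmgb_insert
  if (!is.null(ins) && ins$length > 0 && ins$fraction > 0) {
    hm <- which(cores$class == "HMGB")
    n_ins <- max(1L, round(length(hm) * ins$fraction))
    chosen <- with_seed(seed + 9L, sample(hm, n_ins))
    at <- floor(config$core_length / 2)
    block <- vapply(chosen, function(i)
      with_seed(seed + 10L + i,
                paste(sample(AA, ins$length, replace = TRUE, prob = LG_FREQS),
                      collapse = "")), "")
    names(block) <- cores$id[chosen]
    cores$seq[chosen] <- paste0(substr(cores$seq[chosen], 1, at), block,
                                substr(cores$seq[chosen], at + 1,
                                       nchar(cores$seq[chosen])))
    gapblock <- strrep("-", ins$length)
    aligned <- vapply(seq_len(nrow(cores)), function(i) {
      s <- aligned[i]
      mid <- if (cores$id[i] %in% names(block)) block[[cores$id[i]]] else gapblock
      paste0(substr(s, 1, at), mid, substr(s, at + 1, nchar(s)))
    }, "")
  }

  core_alignment <- new_alignment(cores$id, aligned, class = cores$class)
  fp <- build_full_proteins(cores, config, seed = seed + 11L)

  structure(list(core_sequences = cores, core_alignment = core_alignment,
                 proteins = fp$proteins, domain_end = fp$domain_end,
                 motif = fp$motif, tree = tree,
                 true_ancestors = ev$internal,
                 site_categories = ev$site_categories, config = config),
            class = "hmg_dataset")
}

#' @export
print.hmg_dataset <- function(x, ...) {
  cat("Synthetic HMG-like domain dataset (seed", x$config$seed, ")\n")
  print(table(x$core_sequences$class))
  cat("core alignment:", length(x$core_alignment$id), "x",
      ncol_alignment(x$core_alignment), "; planted motifs:",
      nrow(x$motif), "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits one FASTA per class (full proteins), the core alignment FASTA, the
#' true tree in Newick, a tabular id/class/sequence file, and a JSON ground
#' truth record.
#'
#' @param dataset an `"hmg_dataset"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cls in unique(dataset$proteins$class)) {
    sub <- dataset$proteins[dataset$proteins$class == cls, ]
    write_domain_fasta(sub, file.path(dir, paste0(tolower(cls), ".fasta")))
  }
  write_alignment_fasta(dataset$core_alignment,
                        file.path(dir, "core_alignment.fasta"))
  ape::write.tree(dataset$tree, file.path(dir, "true_tree.nwk"))
  tab <- data.frame(id = dataset$proteins$id, class = dataset$proteins$class,
                    sequence = dataset$proteins$seq)
  write.table(tab, file.path(dir, "sequences.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- list(seed = dataset$config$seed,
             true_tree = ape::write.tree(dataset$tree),
             true_ancestors = as.list(dataset$true_ancestors),
             motif = dataset$motif,
             domain_end = as.list(dataset$domain_end),
             classes = setNames(as.list(dataset$proteins$class),
                                dataset$proteins$id))
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "ground_truth.json"))
  invisible(dir)
}
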