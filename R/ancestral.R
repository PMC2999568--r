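#' Marginal ancestral reconstruction at an internal node
#'
#' Per-site posterior distribution over the 20 residues at a chosen internal
#' node: the tree is re-rooted at that node (legitimate under a reversible
#' model), the posterior is proportional to `pi[state] * partial likelihood`
#' per rate category, and categories are mixed by their per-site posterior
#' weights. The MAP residue string is extracted with alphabetical
#' tie-breaking.
#'
#' @param tree `phylo` with branch lengths (rooted or unrooted).
#' @param aln alignment matching the tips.
#' @param model a [rate_model()].
#' @param node internal node number (ape convention, > number of tips), or
#'   `"root"` for the tree's root node.
#' @return an object of class `"ancestral_reconstruction"`: `node`,
#'   `posterior` (sites x 20), `map` (residue string), `map_prob`.
#' @export
marginal_posteriors <- function(tree, aln, model, node = "root") {
  ntip <- length(tree$tip.label)
  if (identical(node, "root")) {
    phy <- tree
  } else {
    node <- as.integer(node)
    if (is.na(node) || node <= ntip || node > ntip + tree$Nnode)
      stop("node must be an internal node number", call. = FALSE)
    phy <- if (node == ntip + 1L) tree
           else ape::root(tree, node = node, resolve.root = FALSE)
  }
  prep <- prepare_pruning(phy, aln, model)
  r <- run_pruning(prep, prep$phy$edge.length, model, return_root = TRUE)
  nsites <- length(r$sitelik)
  ncat <- length(model$rates)
  post <- matrix(0, nsites, 20, dimnames = list(NULL, AA))
  for (c in seq_len(ncat)) {
    m <- matrix(r$root_partials[, , c], nrow = 20)        # 20 x sites
    post <- post + (1 - model$p_inv) * model$weights[c] *
      t(m * model$pi) * exp(r$root_logscale[, c])
  }
  if (model$p_inv > 0) {
    st <- prep$states
    for (s in seq_len(nsites)) {
      obs <- unique(st[, s]); obs <- obs[obs >= 0L]
      if (length(obs) == 0L) post[s, ] <- post[s, ] + model$p_inv * model$pi
      else if (length(obs) == 1L)
        post[s, obs + 1L] <- post[s, obs + 1L] + model$p_inv * model$pi[obs + 1L]
    }
  }
  post <- post / rowSums(post)
  map_idx <- vapply(seq_len(nsites), function(s) {
    p <- post[s, ]
    cand <- which(p == max(p))
    cand[order(AA[cand])][1]
  }, 0L)
  structure(list(node = node, posterior = post,
                 map = paste(AA[map_idx], collapse = ""),
                 map_prob = post[cbind(seq_len(nsites), map_idx)]),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("Marginal ancestral reconstruction at node",
      if (identical(x$node, "root")) "root" else x$node, "\n")
  cat("  MAP:", x$map, "\n")
  cat("  mean MAP posterior:", round(mean(x$map_prob), 3), "\n")
  invisible(x)
}

#' Reconstruct and compare the ancestors of two domain families
#'
#' For each family: sequences are aligned (unless an alignment is given), a
#' maximum-likelihood tree is fitted, the tree is midpoint-rooted (no
#' outgroup exists within a single class), and the marginal MAP ancestor is
#' reconstructed at the root. The two MAP ancestors are then compared with
#' [compare_consensus()].
#'
#' @param family1,family2 domain sequence data frames (>= 3 sequences each)
#'   or ready `"domain_alignment"` objects.
#' @param model a [rate_model()] (default `LG+G`, alpha 1).
#' @param search tree search passed to [ml_phylogeny()] (default `"none"`,
#'   since the root reconstruction is driven by branch lengths more than by
#'   fine topology).
#' @param ... passed to [compare_consensus()].
#' @return list with `ancestor1`, `ancestor2` (reconstructions), `fit1`,
#'   `fit2`, and `comparison`.
#' @export
reconstruct_family_ancestors <- function(family1, family2,
                                         model = rate_model("LG+G", alpha = 1),
                                         search = "none", ...) {
  one <- function(fam) {
    aln <- if (inherits(fam, "domain_alignment")) fam
           else progressive_align(fam)
    if (length(aln$id) < 3L) stop("each family needs >= 3 sequences",
                                  call. = FALSE)
    fit <- ml_phylogeny(aln, model = model, search = search)
    rooted <- phangorn::midpoint(fit$tree)
    anc <- marginal_posteriors(rooted, aln, model, node = "root")
    list(fit = fit, anc = anc)
  }
  a <- one(family1); b <- one(family2)
  cmp <- compare_consensus(a$anc$map, b$anc$map,
                           ids = c("ancestor1", "ancestor2"), ...)
  list(ancestor1 = a$anc, ancestor2 = b$anc, fit1 = a$fit, fit2 = b$fit,
       comparison = cmp)
}

#' Write an ancestral reconstruction
#'
#' FASTA of the MAP ancestor plus a per-site posterior TSV.
#'
#' @param anc an `"ancestral_reconstruction"`.
#' @param fasta_path,tsv_path output files (skipped when `NULL`).
#' @param id FASTA record id.
#' @export
write_ancestor <- function(anc, fasta_path = NULL, tsv_path = NULL,
                           id = "ancestor") {
  if (!is.null(fasta_path))
    writeLines(paste0(">", id, "\n", anc$map), fasta_path)
  if (!is.null(tsv_path)) {
    d <- data.frame(site = seq_len(nrow(anc$posterior)),
                    map = strsplit(anc$map, "")[[1]],
                    map_prob = anc$map_prob, anc$posterior,
                    check.names = FALSE)
    write.table(d, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(anc)
}
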