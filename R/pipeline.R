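#' Pipeline run configuration
#'
#' Bundles inputs and parameters for [run_pipeline()]. Sequences can come
#' from an in-memory domain sequence data frame (`sequences`), an
#' `"hmg_dataset"`, or per-class FASTA paths.
#'
#' @param sequences domain sequence data frame of core sequences, an
#'   `"hmg_dataset"`, or `NULL`.
#' @param input_files named character vector of per-class FASTA paths
#'   (names are class labels), used when `sequences` is `NULL`.
#' @param aligned optional ready `"domain_alignment"`; when `NULL` the
#'   pipeline aligns with [progressive_align()] (an `"hmg_dataset"` supplies
#'   its core alignment).
#' @param anchor optional `list(row =, start =, end =)` core window for
#'   [extract_core()].
#' @param min_coverage core coverage threshold (default 0.8).
#' @param max_gap_fraction gappy-column threshold (default 0.5).
#' @param model model name (default `"LG+G"`).
#' @param alpha gamma shape (default 0.8).
#' @param gamma_cats gamma categories (default 4).
#' @param elw_replicates,khsh_replicates RELL replicate counts (defaults
#'   1000 and 2000).
#' @param tree_search `"nni"` or `"none"`.
#' @param monophyly_classes class sets whose monophyly is reported.
#' @param motif_pattern PROSITE pattern scanned over full proteins.
#' @param proteins optional domain sequence data frame of full proteins.
#' @param seed RNG seed recorded in every output.
#' @param output_dir optional directory for stage artifacts.
#' @return a `"run_config"` list.
#' @export
run_config <- function(sequences = NULL, input_files = NULL, aligned = NULL,
                       anchor = NULL, min_coverage = 0.8,
                       max_gap_fraction = 0.5, model = "LG+G", alpha = 0.8,
                       gamma_cats = 4, elw_replicates = 1000,
                       khsh_replicates = 2000, tree_search = "nni",
                       monophyly_classes = list(
                         alpha1 = c("ALPHA1_A", "ALPHA1_B"),
                         alpha1_mata = c("ALPHA1_A", "ALPHA1_B", "MATA_HMG")),
                       motif_pattern = "Y-[LMIF]-x(3)-G-[WL]",
                       proteins = NULL, seed = 1, output_dir = NULL) {
  if (!min_coverage > 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]", call. = FALSE)
  if (max_gap_fraction < 0 || max_gap_fraction >= 1)
    stop("max_gap_fraction must be in [0, 1)", call. = FALSE)
  if (inherits(sequences, "hmg_dataset")) {
    ds <- sequences
    sequences <- ds$core_sequences
    if (is.null(aligned)) aligned <- ds$core_alignment
    if (is.null(proteins)) proteins <- ds$proteins
  }
  structure(list(sequences = sequences, input_files = input_files,
                 aligned = aligned, anchor = anchor,
                 min_coverage = min_coverage,
                 max_gap_fraction = max_gap_fraction, model = model,
                 alpha = alpha, gamma_cats = gamma_cats,
                 elw_replicates = elw_replicates,
                 khsh_replicates = khsh_replicates,
                 tree_search = tree_search,
                 monophyly_classes = monophyly_classes,
                 motif_pattern = motif_pattern, proteins = proteins,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the end-to-end analysis
#'
#' Align, core-filter, profile, compare consensuses, infer the ML tree with
#' LR-ELW supports, report monophyly verdicts, test the tree against the
#' rearrangement breaking the alpha1 nesting (KH/SH), reconstruct and
#' compare family ancestors, and scan full proteins for the downstream
#' motif. All randomness derives from `config$seed`.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress? (default FALSE)
#' @return an object of class `"analysis_report"`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[hmgtrace] ", ...)
  warnings_log <- character(0)

  seqs <- config$sequences
  if (is.null(seqs)) {
    if (is.null(config$input_files))
      stop("config carries neither sequences nor input files", call. = FALSE)
    parts <- lapply(names(config$input_files), function(cls) {
      if (!file.exists(config$input_files[[cls]]))
        stop("missing input file: ", config$input_files[[cls]], call. = FALSE)
      read_domain_fasta(config$input_files[[cls]], class = cls)
    })
    seqs <- do.call(rbind, parts)
  }
  if (nrow(seqs) == 0L) stop("no input sequences", call. = FALSE)

  say("aligning ", nrow(seqs), " sequences")
  aln <- if (!is.null(config$aligned)) config$aligned
         else progressive_align(seqs)
  if (!is.null(config$anchor))
    aln <- extract_core(aln, config$anchor$row, config$anchor$start,
                        config$anchor$end)
  cov <- coverage_filter(aln, config$min_coverage)
  if (length(cov$removed_ids))
    warnings_log <- c(warnings_log,
                      paste("coverage filter removed:",
                            paste(cov$removed_ids, collapse = ", ")))
  aln <- remove_gappy_columns(cov$alignment, config$max_gap_fraction)

  say("profiling per class")
  classes <- unique(aln$class)
  profiles <- lapply(classes, function(cls) {
    sub_idx <- aln$class == cls
    column_frequencies(new_alignment(aln$id[sub_idx], aln$seq[sub_idx],
                                     class = cls))
  })
  names(profiles) <- classes
  consensuses <- lapply(profiles, consensus)
  comparisons <- if (length(consensuses) >= 2) {
    all_pairs_comparison(consensuses)
  } else {
    warnings_log <- c(warnings_log,
                      "consensus comparison skipped: fewer than 2 classes survive filtering")
    list()
  }

  say("fitting maximum-likelihood tree")
  model <- rate_model(config$model, alpha = config$alpha,
                      k = config$gamma_cats)
  if (length(aln$id) < 4L) {
    warnings_log <- c(warnings_log,
                      "phylogeny skipped: fewer than 4 sequences survive filtering")
    report <- structure(
      list(seed = config$seed, n_sequences = length(aln$id),
           n_columns = ncol_alignment(aln), removed_ids = cov$removed_ids,
           consensuses = lapply(consensuses, function(x)
             list(class = x$class, seq = x$seq)),
           comparisons = comparisons, fit = NULL, tree_newick = NULL,
           loglik = NA_real_, monophyly = list(), khsh = NULL,
           ancestors = NULL, motif_hits = NULL, warnings = warnings_log,
           provenance = list(package = "hmgtrace",
                             version = as.character(utils::packageVersion("hmgtrace")),
                             model = config$model, alpha = config$alpha,
                             seed = config$seed)),
      class = "analysis_report")
    return(report)
  }
  fit <- ml_phylogeny(aln, model = model, search = config$tree_search)

  monophyly <- lapply(config$monophyly_classes, function(clset) {
    taxa <- aln$id[aln$class %in% clset]
    ok <- is_monophyletic(fit$tree, taxa)
    supp <- NA_real_
    if (ok) {
      ce <- clade_edge(fit$tree, taxa)
      if (!is.na(ce$edge) && ce$tree$edge[ce$edge, 2] >
          length(ce$tree$tip.label)) {
        es <- elw_edge_support(ce$tree, aln, model,
                               n_replicates = config$elw_replicates,
                               seed = config$seed, edges = ce$edge)
        supp <- es$support$support[1]
      }
    }
    list(classes = clset, monophyletic = ok, elw_support = supp)
  })

  say("topology tests")
  khsh <- NULL
  a1_taxa <- aln$id[aln$class %in% c("ALPHA1_A", "ALPHA1_B")]
  ce <- clade_edge(fit$tree, a1_taxa)
  if (!is.na(ce$edge) && ce$tree$edge[ce$edge, 2] > length(ce$tree$tip.label)) {
    alt <- nni_neighbors(ce$tree, ce$edge)[[1]]
    khsh <- tryCatch(
      kh_sh_test(list(fit$tree, alt), aln, model,
                 n_replicates = config$khsh_replicates, seed = config$seed),
      error = function(e) {
        warnings_log <<- c(warnings_log,
                           paste("KH/SH skipped:", conditionMessage(e)))
        NULL
      })
  } else {
    warnings_log <- c(warnings_log,
                      "KH/SH skipped: no internal alpha1 clade edge")
  }

  say("ancestral reconstruction")
  anc <- NULL
  a1_idx <- aln$class %in% c("ALPHA1_A", "ALPHA1_B")
  ma_idx <- aln$class == "MATA_HMG"
  if (sum(a1_idx) >= 3 && sum(ma_idx) >= 3) {
    anc <- reconstruct_family_ancestors(
      new_alignment(aln$id[a1_idx], aln$seq[a1_idx], class = "ALPHA1_A"),
      new_alignment(aln$id[ma_idx], aln$seq[ma_idx], class = "MATA_HMG"),
      model = model)
  } else {
    warnings_log <- c(warnings_log,
                      "ancestor comparison skipped: a family has < 3 members")
  }

  say("motif scan")
  motif_hits <- NULL
  if (!is.null(config$proteins)) {
    hits <- lapply(seq_len(nrow(config$proteins)), function(i)
      scan_pattern(config$proteins$seq[i], config$motif_pattern,
                   id = config$proteins$id[i]))
    motif_hits <- do.call(rbind, hits)
  }

  report <- structure(
    list(seed = config$seed, n_sequences = length(aln$id),
         n_columns = ncol_alignment(aln),
         removed_ids = cov$removed_ids,
         consensuses = lapply(consensuses, function(x)
           list(class = x$class, seq = x$seq)),
         comparisons = comparisons, fit = fit,
         tree_newick = ape::write.tree(fit$tree),
         loglik = fit$loglik, monophyly = monophyly, khsh = khsh,
         ancestors = anc, motif_hits = motif_hits,
         warnings = warnings_log,
         provenance = list(package = "hmgtrace",
                           version = as.character(utils::packageVersion("hmgtrace")),
                           model = config$model, alpha = config$alpha,
                           seed = config$seed)),
    class = "analysis_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    rendered <- report_render(report)
    writeLines(rendered$text, file.path(config$output_dir, "report.txt"))
    writeLines(rendered$json, file.path(config$output_dir, "report.json"))
    ape::write.tree(fit$tree, file.path(config$output_dir, "ml_tree.nwk"))
    write_comparison_tsv(comparisons,
                         file.path(config$output_dir, "comparisons.tsv"))
  }
  report
}

#' Render an analysis report
#'
#' @param report an `"analysis_report"`.
#' @return list with `text` (character vector of lines) and `json`
#'   (schema-stable JSON string).
#' @export
report_render <- function(report) {
  txt <- c(
    "== hmgtrace analysis report ==",
    sprintf("seed %d; %d sequences x %d core columns", report$seed,
            report$n_sequences, report$n_columns),
    sprintf("ML tree log-likelihood: %.4f", report$loglik),
    "",
    "Consensus comparisons:")
  for (cmp in report$comparisons) {
    txt <- c(txt, if (cmp$no_alignment)
      sprintf("  %s vs %s: no significant local alignment", cmp$query,
              cmp$subject)
      else sprintf("  %s vs %s: %.1f%% identity, %.1f%% positives, E = %.2g",
                   cmp$query, cmp$subject, cmp$identity_pct,
                   cmp$positives_pct, cmp$e_value))
  }
  txt <- c(txt, "", "Monophyly verdicts:")
  for (nm in names(report$monophyly)) {
    m <- report$monophyly[[nm]]
    txt <- c(txt, sprintf(
      "  %s (%s): %s%s", nm, paste(m$classes, collapse = "+"),
      if (m$monophyletic) "monophyletic" else "NOT monophyletic",
      if (m$monophyletic && !is.na(m$elw_support))
        sprintf(", LR-ELW support %.1f", m$elw_support) else ""))
  }
  if (!is.null(report$khsh)) {
    txt <- c(txt, "", "Topology tests (vs alpha1-nesting rearrangement):")
    txt <- c(txt, sprintf("  topology %d: lnL %.3f, KH p = %.3f, SH p = %.3f",
                          report$khsh$topology, report$khsh$loglik,
                          report$khsh$kh_p, report$khsh$sh_p))
  }
  if (!is.null(report$ancestors)) {
    cmp <- report$ancestors$comparison
    txt <- c(txt, "", sprintf(
      "Ancestor comparison (alpha1 vs MATA_HMG): %.1f%% identity, %.1f%% positives, E = %.2g",
      cmp$identity_pct, cmp$positives_pct, cmp$e_value))
  }
  txt <- c(txt, "",
           if (is.null(report$motif_hits) || nrow(report$motif_hits) == 0)
             "Motif scan: no matches"
           else c("Motif scan hits:",
                  sprintf("  %s at %d: %s", report$motif_hits$id,
                          report$motif_hits$start, report$motif_hits$match)))
  if (length(report$warnings))
    txt <- c(txt, "", paste("warning:", report$warnings))

  json_obj <- list(
    seed = report$seed, n_sequences = report$n_sequences,
    n_columns = report$n_columns, loglik = report$loglik,
    tree = report$tree_newick,
    consensuses = report$consensuses,
    comparisons = lapply(report$comparisons, function(cmp)
      list(query = cmp$query, subject = cmp$subject,
           identity_pct = cmp$identity_pct,
           positives_pct = cmp$positives_pct, e_value = cmp$e_value)),
    monophyly = report$monophyly,
    khsh = if (!is.null(report$khsh)) report$khsh else NULL,
    ancestor_identity_pct = if (!is.null(report$ancestors))
      report$ancestors$comparison$identity_pct else NULL,
    motif_hits = report$motif_hits,
    provenance = report$provenance)
  list(text = txt,
       json = as.character(jsonlite::toJSON(json_obj, auto_unbox = TRUE,
                                            pretty = TRUE, digits = NA,
                                            null = "null")))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(report_render(x)$text, sep = "\n")
  invisible(x)
}
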