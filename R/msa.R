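#' Gapped alignments
#'
#' An alignment is a list with parallel vectors `id` and `seq` (gapped
#' residue strings of equal length, gap character `-`), plus optional
#' `class` labels, of class `"domain_alignment"`.
#'
#' @param id character ids (unique).
#' @param seq gapped residue strings, all the same length.
#' @param class optional per-row class labels.
#' @return a `"domain_alignment"` object.
#' @export
new_alignment <- function(id, seq, class = NULL) {
  id <- as.character(id); seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ", call. = FALSE)
  if (anyDuplicated(id)) stop("duplicate ids", call. = FALSE)
  w <- unique(nchar(seq))
  if (length(seq) > 0L && length(w) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  structure(list(id = id, seq = seq,
                 class = if (is.null(class)) NULL else rep_len(as.character(class), length(id))),
            class = "domain_alignment")
}

#' @export
print.domain_alignment <- function(x, ...) {
  cat("Alignment:", length(x$id), "rows x", ncol_alignment(x), "columns\n")
  n <- min(6L, length(x$id))
  for (i in seq_len(n))
    cat(sprintf("  %-12s %s\n", x$id[i],
                if (nchar(x$seq[i]) > 60) paste0(substr(x$seq[i], 1, 57), "...") else x$seq[i]))
  if (length(x$id) > n) cat("  ...\n")
  invisible(x)
}

#' @rdname new_alignment
#' @param x an alignment.
#' @export
ncol_alignment <- function(x) if (length(x$seq) == 0L) 0L else nchar(x$seq[1])

#' @rdname new_alignment
#' @export
alignment_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seq, "", fixed = TRUE))
  rownames(m) <- x$id
  m
}

matrix_to_alignment <- function(m, class = NULL)
  new_alignment(rownames(m), apply(m, 1, paste, collapse = ""), class = class)

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Read / write aligned FASTA
#'
#' @param path file path.
#' @param class optional class label for all rows.
#' @export
read_alignment_fasta <- function(path, class = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  new_alignment(sub("\\s.*$", "", names(ss)), as.character(ss), class = class)
}

#' @rdname read_alignment_fasta
#' @param aln an alignment.
#' @export
write_alignment_fasta <- function(aln, path) {
  writeLines(paste0(">", aln$id, "\n", aln$seq), path)
  invisible(path)
}

#' UPGMA guide tree from shared k-mer distances
#'
#' Distance between two sequences is `1 - |shared k-mers| / min(|A|, |B|)`
#' on the sets of distinct k-mers. Clustering is average-linkage (UPGMA).
#'
#' @param seqs domain sequence data frame (>= 2 rows).
#' @param k k-mer length (default 3; sequences shorter than `k` share no
#'   k-mers and get distance 1).
#' @return a rooted `phylo` guide tree whose tips are the sequence ids.
#' @export
build_guide_tree <- function(seqs, k = 3) {
  n <- nrow(seqs)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (anyDuplicated(seqs$id)) stop("duplicate sequence ids", call. = FALSE)
  kmers <- lapply(seqs$seq, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- kmers[[i]]; b <- kmers[[j]]
    dn <- min(length(a), length(b))
    d[i, j] <- d[j, i] <-
      if (dn == 0L) 1 else 1 - length(intersect(a, b)) / dn
  }
  hc <- hclust(as.dist(d), method = "average")
  ape::as.phylo(hc)
}

profile_counts <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(m)
  f <- matrix(0, 20, L, dimnames = list(AA, NULL))
  for (a in seq_along(AA)) f[a, ] <- colSums(m == AA[a])
  f / nrow(m)   # frequencies relative to row count; gap/X mass omitted
}

#' Progressive multiple alignment up a guide tree
#'
#' Aligns sequences by profile-profile global alignment in the order given
#' by a guide tree (children merged before parents). Column scores are the
#' expected substitution score under the two column frequency profiles; gap
#' penalties are unweighted.
#'
#' @param seqs domain sequence data frame.
#' @param guide rooted binary guide tree (`phylo`) with tip labels equal to
#'   the sequence ids; built with [build_guide_tree()] when `NULL`.
#' @param matrix scoring matrix (default [blosum62()]).
#' @param gap_open,gap_extend affine gap penalties (default 11 / 1).
#' @param k k-mer length for the default guide tree.
#' @return a `"domain_alignment"` with rows in input order; removing the
#'   gaps of any row reproduces its input sequence.
#' @export
progressive_align <- function(seqs, guide = NULL, matrix = blosum62(),
                              gap_open = 11, gap_extend = 1, k = 3) {
  if (nrow(seqs) == 1L)
    return(new_alignment(seqs$id, seqs$seq, class = seqs$class))
  if (is.null(guide)) guide <- build_guide_tree(seqs, k = k)
  if (!setequal(guide$tip.label, seqs$id))
    stop("guide tree tips do not match sequence ids", call. = FALSE)
  S20 <- matrix[AA, AA]

  phy <- ape::reorder.phylo(guide, "postorder")
  ntip <- length(phy$tip.label)
  nodes <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) {
    s <- seqs$seq[match(phy$tip.label[i], seqs$id)]
    nodes[[i]] <- list(id = phy$tip.label[i], rows = s)
  }
  parents <- unique(phy$edge[, 1])
  for (p in parents) {
    kids <- phy$edge[phy$edge[, 1] == p, 2]
    acc <- nodes[[kids[1]]]
    for (q in kids[-1]) {
      other <- nodes[[q]]
      f1 <- profile_counts(acc$rows); f2 <- profile_counts(other$rows)
      r <- cpp_profile_align(f1, f2, S20, gap_open, gap_extend)
      path <- r$path
      g1 <- path != 3L; g2 <- path != 2L
      expand <- function(rows, keep) {
        vapply(strsplit(rows, "", fixed = TRUE), function(ch) {
          out <- rep("-", length(keep)); out[keep] <- ch
          paste(out, collapse = "")
        }, "")
      }
      acc <- list(id = c(acc$id, other$id),
                  rows = c(expand(acc$rows, g1), expand(other$rows, g2)))
    }
    nodes[[p]] <- acc
  }
  res <- nodes[[ntip + 1L]]
  ord <- match(seqs$id, res$id)
  new_alignment(seqs$id, res$rows[ord], class = seqs$class)
}

#' Extract the core-region columns around an anchor row window
#'
#' Restricts an alignment to the columns spanned by a window given in the
#' ungapped (1-based, inclusive) coordinates of one anchor row. Insertion
#' columns falling inside the window are retained (use
#' [remove_gappy_columns()] afterwards).
#'
#' @param aln alignment.
#' @param anchor_row id of the anchor row.
#' @param start,end 1-based inclusive window in the anchor row's ungapped
#'   coordinates.
#' @return the restricted alignment.
#' @export
extract_core <- function(aln, anchor_row, start, end) {
  i <- match(anchor_row, aln$id)
  if (is.na(i)) stop("anchor row not found: ", anchor_row, call. = FALSE)
  ch <- strsplit(aln$seq[i], "", fixed = TRUE)[[1]]
  respos <- cumsum(ch != "-")
  n_res <- respos[length(respos)]
  if (start < 1 || end > n_res || start > end)
    stop("window outside anchor row (length ", n_res, ")", call. = FALSE)
  ## columns between the anchor's start-th and end-th residues, inclusive
  first <- which(respos == start & ch != "-")[1]
  last <- which(respos == end & ch != "-")[1]
  keep <- seq(first, last)
  m <- alignment_matrix(aln)[, keep, drop = FALSE]
  matrix_to_alignment(m, class = aln$class)
}

#' Remove rows with insufficient core coverage
#'
#' A row is removed when its count of non-gap residues across the core
#' columns, divided by `core_length`, falls strictly below `min_coverage`;
#' coverage exactly at the threshold is kept. This mirrors the study's rule
#' of discarding sequences covering less than 80% of the ~40-residue core.
#'
#' @param aln core-region alignment (non-empty).
#' @param min_coverage coverage threshold in `(0, 1]` (default 0.8).
#' @param core_length denominator for the coverage fraction; defaults to the
#'   alignment's column count.
#' @return list with the filtered `alignment` and the `removed_ids`.
#' @export
coverage_filter <- function(aln, min_coverage = 0.8, core_length = NULL) {
  if (length(aln$id) == 0L) stop("empty alignment", call. = FALSE)
  if (!is.numeric(min_coverage) || min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]", call. = FALSE)
  if (is.null(core_length)) core_length <- ncol_alignment(aln)
  nongap <- nchar(gsub("-", "", aln$seq, fixed = TRUE))
  keep <- (nongap / core_length) >= min_coverage
  filtered <- new_alignment(aln$id[keep], aln$seq[keep],
                            class = if (is.null(aln$class)) NULL else aln$class[keep])
  list(alignment = filtered, removed_ids = aln$id[!keep])
}

#' Delete columns dominated by gaps
#'
#' Columns whose gap fraction strictly exceeds `max_gap_fraction` are
#' deleted (the study removed a variable-size insert section present in a
#' minority of HMGB rows). Column order is otherwise preserved.
#'
#' @param aln alignment.
#' @param max_gap_fraction threshold in `[0, 1)` (default 0.5).
#' @return the column-filtered alignment.
#' @export
remove_gappy_columns <- function(aln, max_gap_fraction = 0.5) {
  if (length(aln$id) == 0L) stop("empty alignment", call. = FALSE)
  if (max_gap_fraction < 0 || max_gap_fraction >= 1)
    stop("max_gap_fraction must be in [0, 1)", call. = FALSE)
  m <- alignment_matrix(aln)
  gapfrac <- colMeans(m == "-")
  matrix_to_alignment(m[, gapfrac <= max_gap_fraction, drop = FALSE],
                      class = aln$class)
}

#' Positional frequency profile and information content
#'
#' Per-column amino-acid frequencies `(count + pseudocount) /
#' (non-gap total + 20 * pseudocount)` (gaps and `X` excluded from counts and
#' denominators) and information content `log2(20) - H` in bits, the
#' quantity a sequence logo displays. All-gap columns get uniform
#' frequencies, information content 0, and are flagged.
#'
#' @param aln alignment (non-empty).
#' @param pseudocount nonnegative pseudocount (default 0).
#' @return an object of class `"position_profile"`: `freq` (20 x L),
#'   `counts`, `ic` (bits), `n_sequences`, `pseudocount`, `all_gap` flags.
#' @export
column_frequencies <- function(aln, pseudocount = 0) {
  if (length(aln$id) == 0L) stop("empty alignment", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be nonnegative", call. = FALSE)
  m <- alignment_matrix(aln)
  L <- ncol(m)
  counts <- matrix(0, 20, L, dimnames = list(AA, NULL))
  for (a in seq_along(AA)) counts[a, ] <- colSums(m == AA[a])
  tot <- colSums(counts)
  all_gap <- tot == 0
  denom <- tot + 20 * pseudocount
  freq <- sweep(counts + pseudocount, 2, ifelse(denom > 0, denom, 1), "/")
  freq[, all_gap] <- 1 / 20
  h <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  ic <- log2(20) - h
  ic[all_gap] <- 0
  structure(list(freq = freq, counts = counts, ic = ic,
                 n_sequences = length(aln$id), pseudocount = pseudocount,
                 all_gap = all_gap,
                 class_label = if (!is.null(aln$class)) aln$class[1] else NA_character_),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat("Position profile:", ncol(x$freq), "columns from", x$n_sequences,
      "sequences\n")
  cat("  mean information content:", round(mean(x$ic), 3), "bits\n")
  invisible(x)
}

#' Consensus sequence of a profile
#'
#' Modal residue per column (ties broken alphabetically by one-letter code),
#' with the modal frequency as per-position support.
#'
#' @param profile a [column_frequencies()] profile.
#' @param class_label optional class label to attach.
#' @return an object of class `"consensus_seq"`: `seq`, `support`, `class`.
#' @export
consensus <- function(profile, class_label = profile$class_label) {
  ## ties break alphabetically by one-letter code, not by matrix order
  idx <- vapply(seq_len(ncol(profile$freq)), function(j) {
    f <- profile$freq[, j]
    cand <- which(f == max(f))
    cand[order(AA[cand])][1]
  }, 0L)
  structure(list(seq = paste(AA[idx], collapse = ""),
                 support = profile$freq[cbind(idx, seq_along(idx))],
                 class = class_label),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat("Consensus", if (!is.na(x$class)) paste0("(", x$class, ")") else "", ":\n  ",
      x$seq, "\n  mean support ", round(mean(x$support), 3), "\n", sep = "")
  invisible(x)
}

#' Write a profile TSV
#'
#' One row per column: index, the 20 residue frequencies, information
#' content in bits, consensus residue and its support.
#'
#' @param profile a position profile.
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  cons <- consensus(profile)
  d <- data.frame(column = seq_len(ncol(profile$freq)),
                  t(profile$freq), ic_bits = profile$ic,
                  consensus = strsplit(cons$seq, "")[[1]],
                  support = cons$support, check.names = FALSE)
  names(d)[2:21] <- AA
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
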