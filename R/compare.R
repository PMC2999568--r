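#' Compare two consensus (or ancestral) sequences
#'
#' Local affine-gap alignment of two residue strings scored with a
#' substitution matrix, summarized BLAST-style: percent identity, percent
#' positives (aligned pairs with matrix score > 0, identities included), raw
#' and bit score, and a Karlin-Altschul E-value
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' The default gapped BLOSUM62 statistical parameters are lambda = 0.267,
#' K = 0.041; search-space sizes `m`, `n` default to the two sequence
#' lengths (pairwise mode, no composition adjustment).
#'
#' @param c1,c2 `"consensus_seq"` objects or plain residue strings.
#' @param matrix scoring matrix (default [blosum62()]).
#' @param gap_open,gap_extend affine gap penalties (default 11 / 1).
#' @param lambda_,k_const Karlin-Altschul parameters.
#' @param m,n search-space sizes (default: the sequence lengths).
#' @param ids optional `c(query, subject)` labels.
#' @return an object of class `"comparison_result"` with fields `query`,
#'   `subject`, `length`, `n_identical`, `n_positive`, `identity_pct`,
#'   `positives_pct`, `score`, `bit_score`, `e_value`, `m`, `n`,
#'   `no_alignment` (flag), and the gapped segment strings.
#' @examples
#' compare_consensus("MKKRTAWLNE", "MKRRSAWINE")
#' @export
compare_consensus <- function(c1, c2, matrix = blosum62(), gap_open = 11,
                              gap_extend = 1, lambda_ = 0.267,
                              k_const = 0.041, m = NULL, n = NULL,
                              ids = c("query", "subject")) {
  s1 <- if (inherits(c1, "consensus_seq")) c1$seq else as.character(c1)
  s2 <- if (inherits(c2, "consensus_seq")) c2$seq else as.character(c2)
  if (!nzchar(s1) || !nzchar(s2)) stop("empty consensus", call. = FALSE)
  if (inherits(c1, "consensus_seq") && !is.null(c1$class) && !is.na(c1$class))
    ids[1] <- c1$class
  if (inherits(c2, "consensus_seq") && !is.null(c2$class) && !is.na(c2$class))
    ids[2] <- c2$class
  if (is.null(m)) m <- nchar(s1)
  if (is.null(n)) n <- nchar(s2)

  # align in a canonical order so tie-broken optima (and hence identity and
  # positive counts) are invariant under query/subject swaps
  swapped <- s2 < s1
  al <- if (swapped) {
    x <- pairwise_align(s2, s1, matrix = matrix, gap_open = gap_open,
                        gap_extend = gap_extend, mode = "local")
    x[c("a", "b")] <- x[c("b", "a")]
    x[c("a_start", "b_start")] <- x[c("b_start", "a_start")]
    x
  } else {
    pairwise_align(s1, s2, matrix = matrix, gap_open = gap_open,
                   gap_extend = gap_extend, mode = "local")
  }
  if (al$empty) {
    out <- list(query = ids[1], subject = ids[2], length = 0L,
                n_identical = 0L, n_positive = 0L, identity_pct = NA_real_,
                positives_pct = NA_real_, score = 0,
                bit_score = NA_real_, e_value = NA_real_, m = m, n = n,
                no_alignment = TRUE, aligned = c("", ""))
    class(out) <- "comparison_result"
    return(out)
  }
  a <- strsplit(al$a, "")[[1]]; b <- strsplit(al$b, "")[[1]]
  len <- length(a)
  paired <- a != "-" & b != "-"
  ident <- sum(paired & a == b)
  pos <- sum(paired & matrix[cbind(a[paired], b[paired])] > 0)
  bit <- (lambda_ * al$score - log(k_const)) / log(2)
  ev <- k_const * m * n * exp(-lambda_ * al$score)
  out <- list(query = ids[1], subject = ids[2], length = len,
              n_identical = ident, n_positive = pos,
              identity_pct = 100 * ident / len,
              positives_pct = 100 * pos / len,
              score = al$score, bit_score = bit, e_value = ev, m = m, n = n,
              no_alignment = FALSE, aligned = c(al$a, al$b))
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$query, "vs", x$subject, "\n")
  if (x$no_alignment) {
    cat("  no significant local alignment\n")
  } else {
    cat(sprintf("  length %d: %.1f%% identity (%d), %.1f%% positives (%d)\n",
                x$length, x$identity_pct, x$n_identical, x$positives_pct,
                x$n_positive))
    cat(sprintf("  raw score %.1f, bit score %.1f, E = %.2g\n",
                x$score, x$bit_score, x$e_value))
  }
  invisible(x)
}

#' All-pairs consensus comparison
#'
#' One [compare_consensus()] result per unordered pair.
#'
#' @param consensuses list of `"consensus_seq"` objects (>= 2), ideally
#'   named by class.
#' @param ... passed to [compare_consensus()].
#' @return list of `"comparison_result"` objects.
#' @export
all_pairs_comparison <- function(consensuses, ...) {
  kk <- length(consensuses)
  if (kk < 2L) stop("need at least 2 consensuses", call. = FALSE)
  nm <- names(consensuses)
  if (is.null(nm)) nm <- paste0("consensus", seq_len(kk))
  pairs <- combn(kk, 2)
  lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    compare_consensus(consensuses[[i]], consensuses[[j]],
                      ids = c(nm[i], nm[j]), ...)
  })
}

#' Write comparison results as a BLAST-like TSV
#'
#' Columns: qid, sid, pident, ppos, length, bitscore, evalue.
#'
#' @param results list of comparison results.
#' @param path output file.
#' @export
write_comparison_tsv <- function(results, path) {
  d <- do.call(rbind, lapply(results, function(r)
    data.frame(qid = r$query, sid = r$subject,
               pident = round(r$identity_pct, 2),
               ppos = round(r$positives_pct, 2), length = r$length,
               bitscore = round(r$bit_score, 1),
               evalue = signif(r$e_value, 2))))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
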