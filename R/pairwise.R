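#' BLOSUM62 scoring matrix
#'
#' The standard BLOSUM62 substitution matrix (from Biostrings' distributed
#' copy), restricted by default to the 20 canonical residues plus `X`.
#'
#' @param extended keep the full 25-letter matrix (B, J, Z, X, `*`)?
#' @return integer scoring matrix with residue dimnames.
#' @export
blosum62 <- function(extended = FALSE) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  if (!extended) {
    keep <- c(AA, "X")
    m <- m[keep, keep]
  }
  m
}

seq_to_idx <- function(s, matrix) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(ch, rownames(matrix))
  if (anyNA(idx)) {
    bad <- unique(ch[is.na(idx)])
    stop("residue(s) with no scoring-matrix entry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  idx - 1L
}

apply_path <- function(a_chars, b_chars, path, a_start = 1L, b_start = 1L) {
  ga <- character(length(path)); gb <- character(length(path))
  i <- a_start; j <- b_start
  for (k in seq_along(path)) {
    if (path[k] == 1L) { ga[k] <- a_chars[i]; gb[k] <- b_chars[j]; i <- i + 1L; j <- j + 1L }
    else if (path[k] == 2L) { ga[k] <- a_chars[i]; gb[k] <- "-"; i <- i + 1L }
    else { ga[k] <- "-"; gb[k] <- b_chars[j]; j <- j + 1L }
  }
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""))
}

#' Optimal pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch (global) or Smith-Waterman (local) alignment under the
#' Gotoh affine-gap recursion. A gap of length L costs
#' `gap_open + L * gap_extend` (so the first gap residue pays both).
#'
#' @param a,b residue strings (non-empty).
#' @param matrix scoring matrix with residue dimnames; default [blosum62()].
#' @param gap_open,gap_extend positive gap penalties (default 11 / 1, the
#'   BLASTP defaults).
#' @param mode `"global"` or `"local"`.
#' @return a list of class `"pairwise_alignment"`: `score`, gapped strings
#'   `a` and `b`, 1-based `a_start`/`b_start` of the aligned segment, and
#'   `empty` (`TRUE` when local alignment finds no positive-scoring pair).
#' @examples
#' pairwise_align("MKKRW", "MKRW")
#' @export
pairwise_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                           gap_extend = 1, mode = c("global", "local")) {
  mode <- match.arg(mode)
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  ai <- seq_to_idx(a, matrix); bi <- seq_to_idx(b, matrix)
  r <- cpp_pairwise(ai, bi, matrix, gap_open, gap_extend, mode == "local")
  if (isTRUE(r$empty)) {
    out <- list(score = 0, a = "", b = "", a_start = NA_integer_,
                b_start = NA_integer_, empty = TRUE, mode = mode)
  } else {
    g <- apply_path(strsplit(a, "")[[1]], strsplit(b, "")[[1]], r$path,
                    r$a_start, r$b_start)
    out <- list(score = r$score, a = g$a, b = g$b, a_start = r$a_start,
                b_start = r$b_start, empty = FALSE, mode = mode)
  }
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$mode, "alignment, score", format(x$score), "\n")
  if (x$empty) cat("  (no significant local alignment)\n")
  else cat(" ", x$a, "\n ", x$b, "\n")
  invisible(x)
}
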