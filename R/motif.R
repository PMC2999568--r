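#' Parse a PROSITE-style pattern
#'
#' Supported subset: literal residues, residue sets `[..]`, negated sets
#' `{..}`, the wildcard `x`, and repeated wildcards `x(n)` / `x(n,m)`,
#' joined with `-`. The motif characterized downstream of the alpha1 domain,
#' `Y-[LMIF]-x(3)-G-[WL]`, parses to six elements spanning a minimum of 7
#' residues.
#'
#' @param text pattern string.
#' @return an object of class `"prosite_pattern"`: `elements` (list of
#'   `type`/`residues`/`min`/`max`), `min_length`, normalized `text`.
#' @examples
#' parse_pattern("Y-[LMIF]-x(3)-G-[WL]")
#' @export
parse_pattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("pattern must be a non-empty string", call. = FALSE)
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  offset <- 0L
  elements <- lapply(parts, function(p) {
    pos <- offset + 1L
    offset <<- offset + nchar(p) + 1L
    if (grepl("^[A-WYZ]$", p) && p != "X") {
      if (!p %in% AA)
        stop("unknown residue '", p, "' at position ", pos, call. = FALSE)
      return(list(type = "literal", residues = p, min = 1L, max = 1L))
    }
    if (p == "x" || p == "X")
      return(list(type = "wildcard", residues = NULL, min = 1L, max = 1L))
    m <- regmatches(p, regexec("^[xX]\\((\\d+)(,(\\d+))?\\)$", p))[[1]]
    if (length(m)) {
      lo <- as.integer(m[2])
      hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
      if (hi < lo) stop("empty repeat range at position ", pos, call. = FALSE)
      return(list(type = "wildcard", residues = NULL, min = lo, max = hi))
    }
    m <- regmatches(p, regexec("^\\[([A-Z]+)\\]$", p))[[1]]
    if (length(m)) {
      res <- strsplit(m[2], "")[[1]]
      if (!all(res %in% AA))
        stop("unknown residue in set at position ", pos, call. = FALSE)
      return(list(type = "set", residues = res, min = 1L, max = 1L))
    }
    m <- regmatches(p, regexec("^\\{([A-Z]+)\\}$", p))[[1]]
    if (length(m)) {
      res <- strsplit(m[2], "")[[1]]
      if (!all(res %in% AA))
        stop("unknown residue in negated set at position ", pos, call. = FALSE)
      return(list(type = "negated", residues = res, min = 1L, max = 1L))
    }
    stop("malformed pattern element '", p, "' at position ", pos,
         call. = FALSE)
  })
  norm <- vapply(elements, function(e) {
    span <- if (e$min == e$max) {
      if (e$min == 1L) "" else paste0("(", e$min, ")")
    } else paste0("(", e$min, ",", e$max, ")")
    switch(e$type,
           literal = e$residues,
           wildcard = paste0("x", span),
           set = paste0("[", paste(e$residues, collapse = ""), "]"),
           negated = paste0("{", paste(e$residues, collapse = ""), "}"))
  }, "")
  structure(list(elements = elements,
                 min_length = sum(vapply(elements, `[[`, 0L, "min")),
                 text = paste(norm, collapse = "-")),
            class = "prosite_pattern")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("PROSITE pattern:", x$text, "\n")
  cat("  ", length(x$elements), "elements, minimum length", x$min_length, "\n")
  invisible(x)
}

pattern_regex <- function(pattern) {
  paste(vapply(pattern$elements, function(e) {
    span <- if (e$min == e$max) {
      if (e$min == 1L) "" else paste0("{", e$min, "}")
    } else paste0("{", e$min, ",", e$max, "}")
    base <- switch(e$type,
                   literal = e$residues,
                   wildcard = "[A-Z]",
                   set = paste0("[", paste(e$residues, collapse = ""), "]"),
                   negated = paste0("[^", paste(e$residues, collapse = ""), "]"))
    paste0(base, span)
  }, ""), collapse = "")
}

#' Scan a sequence for a PROSITE pattern
#'
#' Reports all matches (or the leftmost non-overlapping ones) with 1-based
#' start positions in ascending order; at each start the shortest match is
#' reported. Matching is case-insensitive.
#'
#' @param seq residue string, or a one-row domain sequence data frame.
#' @param pattern a [parse_pattern()] result or pattern string.
#' @param overlap report overlapping matches? (default TRUE)
#' @param id sequence id used in the output.
#' @return data frame with columns `id`, `start`, `end`, `match` (zero rows
#'   when there is no match).
#' @examples
#' scan_pattern("AYLNLAGW", "Y-[LMIF]-x(3)-G-[WL]")
#' @export
scan_pattern <- function(seq, pattern, overlap = TRUE, id = "seq") {
  if (is.data.frame(seq)) { id <- seq$id[1]; seq <- seq$seq[1] }
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  s <- toupper(seq)
  rx <- pattern_regex(pattern)
  # lookahead finds every (overlapping) start; lazy quantifiers would not
  # change the start set, so match length is resolved per start below
  starts <- gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1]]
  if (starts[1] == -1L)
    return(data.frame(id = character(0), start = integer(0),
                      end = integer(0), match = character(0)))
  lazy_rx <- paste0("^(", gsub("}", "}?", rx, fixed = TRUE), ")")
  out <- lapply(as.integer(starts), function(p) {
    tail_s <- substr(s, p, nchar(s))
    m <- regmatches(tail_s, regexpr(lazy_rx, tail_s, perl = TRUE))
    data.frame(id = id, start = p, end = p + nchar(m) - 1L, match = m)
  })
  res <- do.call(rbind, out)
  if (!overlap) {
    keep <- logical(nrow(res)); last_end <- 0L
    for (i in seq_len(nrow(res))) {
      if (res$start[i] > last_end) { keep[i] <- TRUE; last_end <- res$end[i] }
    }
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Extract the window downstream of a domain
#'
#' The subsequence from `domain_end + 1` to `domain_end + window` (shorter
#' at the protein end). An empty window — a protein stopping at the domain
#' end — is returned zero-length with `flagged = TRUE`.
#'
#' @param seq residue string or one-row domain sequence data frame.
#' @param domain_end 1-based inclusive last position of the domain.
#' @param window window length (default 60, the span of the conserved
#'   region adjacent to the alpha1 domain).
#' @return list: `seq` (possibly empty string), `start`, `length`,
#'   `flagged`.
#' @export
downstream_window <- function(seq, domain_end, window = 60) {
  if (is.data.frame(seq)) seq <- seq$seq[1]
  L <- nchar(seq)
  if (domain_end > L || domain_end < 0)
    stop("domain_end outside the sequence", call. = FALSE)
  if (domain_end == L)
    return(list(seq = "", start = NA_integer_, length = 0L, flagged = TRUE))
  to <- min(domain_end + window, L)
  sub <- substr(seq, domain_end + 1L, to)
  list(seq = sub, start = domain_end + 1L, length = nchar(sub),
       flagged = FALSE)
}

#' Analytic expected hit count of a pattern
#'
#' Under i.i.d. residues with the given frequencies, the per-window match
#' probability is the product over pattern positions of the allowed-set
#' probability (taken at each element's minimum span), and the expected hit
#' count is that probability times the number of windows,
#' `seq_length - min_length + 1`.
#'
#' @param pattern a [parse_pattern()] result or pattern string.
#' @param seq_length sequence length.
#' @param residue_freqs 20-vector of residue frequencies summing to 1
#'   (default uniform), in the order `A R N D C Q E G H I L K M F P S T W Y V`.
#' @return list: `p_window` (per-window match probability at minimum span)
#'   and `expected` (expected number of hits).
#' @examples
#' expected_hits("Y-[LMIF]-x(3)-G-[WL]", 1e6)$p_window  # 2e-05 under uniform
#' @export
expected_hits <- function(pattern, seq_length, residue_freqs = rep(1 / 20, 20)) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  if (abs(sum(residue_freqs) - 1) > 1e-8)
    stop("residue frequencies must sum to 1", call. = FALSE)
  freqs <- setNames(as.numeric(residue_freqs), AA)
  p <- prod(vapply(pattern$elements, function(e) {
    pe <- switch(e$type,
                 literal = freqs[e$residues],
                 wildcard = 1,
                 set = sum(freqs[e$residues]),
                 negated = 1 - sum(freqs[e$residues]))
    pe ^ e$min
  }, 0))
  nwin <- max(seq_length - pattern$min_length + 1, 0)
  list(p_window = unname(p), expected = unname(p * nwin))
}
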