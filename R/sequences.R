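#' Domain sequence sets
#'
#' A domain sequence set is a plain data frame with columns `id`, `taxon`,
#' `class` and `seq` holding ungapped upper-case protein sequences over the
#' 20-letter amino-acid alphabet (plus `X` for unknown residues). These are
#' the units the profiling and phylogenetic stages consume.
#'
#' @param id character vector of unique accession-like identifiers.
#' @param seq character vector of residues, same length as `id`.
#' @param class domain class label, one of `"ALPHA1_A"`, `"ALPHA1_B"`,
#'   `"MATA_HMG"`, `"SOX"`, `"HMGB"`, `"UNKNOWN"` (recycled).
#' @param taxon optional taxon labels (recycled; defaults to `id`).
#' @return a `data.frame` with columns `id`, `taxon`, `class`, `seq`.
#' @examples
#' domain_sequences(c("s1", "s2"), c("MKKR", "MKTR"), class = "MATA_HMG")
#' @export
domain_sequences <- function(id, seq, class = "UNKNOWN", taxon = id) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ", call. = FALSE)
  if (anyDuplicated(id)) stop("duplicate sequence ids", call. = FALSE)
  if (any(nchar(seq) == 0L)) stop("empty sequences not allowed", call. = FALSE)
  bad <- grepl(paste0("[^", paste(AA, collapse = ""), "X]"), seq)
  if (any(bad))
    stop("invalid residues (not amino-acid letters or X) in: ",
         paste(head(id[bad], 3), collapse = ", "), call. = FALSE)
  class <- rep_len(as.character(class), length(id))
  if (!all(class %in% DOMAIN_CLASSES))
    stop("unknown domain class; expected one of ",
         paste(DOMAIN_CLASSES, collapse = ", "), call. = FALSE)
  data.frame(id = id, taxon = rep_len(as.character(taxon), length(id)),
             class = class, seq = seq, stringsAsFactors = FALSE)
}

#' Read domain sequences from FASTA
#'
#' Reads (possibly line-wrapped) protein FASTA. Gap characters are rejected;
#' the class can be given per file.
#'
#' @param path FASTA file.
#' @param class domain class label applied to all records.
#' @return a domain sequence data frame (see [domain_sequences()]).
#' @export
read_domain_fasta <- function(path, class = "UNKNOWN") {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("gap characters in FASTA; use read_alignment_fasta() for aligned input",
         call. = FALSE)
  domain_sequences(ids, seqs, class = class)
}

#' Write domain sequences to FASTA
#'
#' @param seqs domain sequence data frame.
#' @param path output file.
#' @export
write_domain_fasta <- function(seqs, path) {
  writeLines(paste0(">", seqs$id, "\n", seqs$seq), path)
  invisible(path)
}

#' Read a tabular (id, class, sequence) domain table
#'
#' Reads CSV or TSV (by extension, or `sep`) with columns `id`, `class`,
#' `sequence` (or `seq`), the exported shape of the study's per-class
#' supplementary sequence sets.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return a domain sequence data frame.
#' @export
read_domain_table <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  seqcol <- intersect(c("sequence", "seq"), names(d))[1]
  if (!all(c("id", "class") %in% names(d)) || is.na(seqcol))
    stop("table needs columns id, class, sequence", call. = FALSE)
  domain_sequences(d$id, d[[seqcol]], class = d$class,
                   taxon = if ("taxon" %in% names(d)) d$taxon else d$id)
}

#' Tally per-class record counts
#'
#' Convenience check mirroring the study's dataset bookkeeping: counts
#' records per domain class and the total.
#'
#' @param seqs domain sequence data frame.
#' @return named integer vector of per-class counts with a `total` entry.
#' @export
check_class_counts <- function(seqs) {
  counts <- table(factor(seqs$class, levels = DOMAIN_CLASSES))
  out <- c(as.integer(counts), sum(counts))
  names(out) <- c(DOMAIN_CLASSES, "total")
  out
}
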