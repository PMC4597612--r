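# Thin readers/writers for the plain-text formats the pipeline exchanges:
# FASTA (via Biostrings), BED intervals, and TSV tables. Coordinates in
# BED files are 0-based half-open, matching the in-memory convention.

#' Read a (multi-)FASTA file
#'
#' @param path File path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (or list of `rna_seq`).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs)) {
    seqs <- stats::setNames(
      vapply(seqs, function(s) if (inherits(s, "rna_seq")) s$residues else s,
             character(1)),
      vapply(seqs, function(s) if (inherits(s, "rna_seq")) s$id else "",
             character(1)))
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a BED file (3 or 6 columns)
#'
#' @param path File path.
#' @return `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(x))]
  x
}

#' Write intervals to BED
#'
#' @param x `data.frame` with at least `chrom`, `start`, `end`; `name`,
#'   `score`, `strand` written when present.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV table with a header row
#'
#' @param path File path.
#' @param row_names Logical; first column holds row names.
#' @return `data.frame`.
#' @export
read_tsv <- function(path, row_names = FALSE) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    row.names = if (row_names) 1L else NULL,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a TSV table with a header row
#'
#' @param x `data.frame`.
#' @param path Output path.
#' @param row_names Logical; write row names as a leading column.
#' @export
write_tsv <- function(x, path, row_names = FALSE) {
  if (row_names) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
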