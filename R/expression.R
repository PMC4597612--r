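# Small-RNA arm counting, arm dominance, expression calls and the
# co-expression rule used to infer independent intragenic promoter
# activity.
#
# The promoter inference is categorical evidence, not proof: observing the
# miRNA without its host (and never the host without the miRNA) supports,
# but does not demonstrate, an independent promoter.

#' Count small-RNA reads per precursor arm
#'
#' Each read is aligned ungapped against the precursor at every offset;
#' its best placements are those with the fewest mismatches (at most
#' `max_mismatch`, otherwise the read is unassigned). A read is assigned
#' to the arm covering at least `min_overlap` of its best placement; reads
#' whose best placements are split between the two arms, or that overlap
#' neither arm sufficiently, are tallied as `count_other` (multi-mapping
#' reads are excluded rather than fractionally assigned).
#'
#' @param reads Character vector of read sequences (16-30 nt; DNA or RNA).
#' @param precursor The precursor sequence (`rna_seq` or character).
#' @param arms A `mature_arms`.
#' @param max_mismatch Maximum mismatches for a valid placement.
#' @param min_overlap Minimum read/arm overlap (nt) for arm assignment.
#' @return An `arm_counts`: `count5p`, `count3p`, `count_other`,
#'   `unassigned`, `total` (the first four sum to `total`).
#' @export
count_arm_reads <- function(reads, precursor, arms, max_mismatch = 1L,
                            min_overlap = 16L) {
  precursor <- as_rna_seq(precursor)
  P <- .chars(precursor$residues)
  L <- length(P)
  c5 <- c3 <- other <- unassigned <- 0L
  for (rd in reads) {
    R <- .chars(rna_seq(rd)$residues)
    m <- length(R)
    if (m < 16L || m > 30L) stop("read length outside 16-30 nt: ", rd)
    if (m > L) { unassigned <- unassigned + 1L; next }
    offs <- seq_len(L - m + 1L)
    mm <- vapply(offs, function(o) sum(P[o:(o + m - 1L)] != R), integer(1))
    best <- min(mm)
    if (best > max_mismatch) { unassigned <- unassigned + 1L; next }
    placements <- offs[mm == best]
    arms_hit <- unique(unlist(lapply(placements, function(o) {
      iv <- c(o - 1L, o - 1L + m)
      hit <- character(0)
      if (.iv_overlap(iv, arms$arm5p) >= min_overlap) hit <- c(hit, "5p")
      if (.iv_overlap(iv, arms$arm3p) >= min_overlap) hit <- c(hit, "3p")
      if (!length(hit)) hit <- "none"
      hit
    })))
    arms_hit <- setdiff(arms_hit, if (length(arms_hit) > 1L) "none" else character(0))
    if (identical(arms_hit, "5p")) c5 <- c5 + 1L
    else if (identical(arms_hit, "3p")) c3 <- c3 + 1L
    else other <- other + 1L
  }
  structure(list(count5p = c5, count3p = c3, count_other = other,
                 unassigned = unassigned, total = length(reads)),
            class = "arm_counts")
}

#' 3p arm dominance
#'
#' Fraction of arm-assigned reads on the 3p arm.
#'
#' @param counts An `arm_counts` (or a list with `count5p`, `count3p`).
#' @return `count3p / (count5p + count3p)`.
#' @examples
#' arm_dominance(list(count5p = 2, count3p = 10))  # 0.833...
#' @export
arm_dominance <- function(counts) {
  tot <- counts$count5p + counts$count3p
  if (tot <= 0) stop("dominance undefined: no reads assigned to either arm")
  counts$count3p / tot
}

#' Call expression from per-sample values
#'
#' Microarray: provided present/absent flags (`"P"`/`"A"`) pass through;
#' numeric values are treated as detection p-values and called present
#' below `p_cutoff`. RNA-seq: values at or above `threshold` (FPKM) are
#' present. `NA` values yield `"missing"`.
#'
#' @param values Character (`P`/`A`) or numeric vector.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param threshold RNA-seq presence floor (FPKM).
#' @param p_cutoff Microarray detection p-value cutoff.
#' @return Character vector over `present`/`absent`/`missing`, same
#'   length and names as `values`.
#' @export
call_expression <- function(values, platform = c("microarray", "rnaseq"),
                            threshold = 1.0, p_cutoff = 0.05) {
  platform <- match.arg(platform)
  out <- if (platform == "microarray" && is.character(values)) {
    ifelse(values == "P", "present", ifelse(values == "A", "absent", NA))
  } else if (platform == "microarray") {
    ifelse(as.numeric(values) < p_cutoff, "present", "absent")
  } else {
    ifelse(as.numeric(values) >= threshold, "present", "absent")
  }
  out[is.na(values) | is.na(out)] <- "missing"
  names(out) <- names(values)
  out
}

#' Reduce miRNA and host calls to a 2x2 co-expression table
#'
#' @param mirna_calls,host_calls Character vectors over
#'   `present`/`absent`/`missing`, same length (same samples). Samples
#'   missing in either gene are dropped.
#' @return A `coexpression_table`: counts `both`, `mirna_only`,
#'   `host_only`, `neither` (summing to the jointly assayed samples).
#' @export
coexpression_table <- function(mirna_calls, host_calls) {
  stopifnot(length(mirna_calls) == length(host_calls))
  ok <- mirna_calls %in% c("present", "absent") &
    host_calls %in% c("present", "absent")
  m <- mirna_calls[ok] == "present"
  h <- host_calls[ok] == "present"
  structure(list(both = sum(m & h), mirna_only = sum(m & !h),
                 host_only = sum(!m & h), neither = sum(!m & !h),
                 n = sum(ok)), class = "coexpression_table")
}

#' Infer the transcription mode of an intronic miRNA
#'
#' Categorical rule over the 2x2 co-expression table:
#' miRNA observed without the host (and never host without miRNA) supports
#' an independent intragenic promoter; host without miRNA violates the
#' expectation that host transcription always yields the miRNA and is
#' reported rather than suppressed; miRNA only ever with the host is
#' host-coupled; no expression at all is inconclusive.
#'
#' @param tab A `coexpression_table` (or list with the four counts).
#' @return One of `"independent_promoter_supported"`,
#'   `"expectation_violated"`, `"host_coupled_only"`, `"inconclusive"`.
#' @export
infer_transcription_modes <- function(tab) {
  cts <- c(tab$both, tab$mirna_only, tab$host_only, tab$neither)
  if (any(cts < 0)) stop("negative counts in co-expression table")
  if (sum(cts) == 0) stop("empty co-expression table")
  if (tab$host_only > 0) return("expectation_violated")
  if (tab$mirna_only > 0) return("independent_promoter_supported")
  if (tab$both > 0) return("host_coupled_only")
  "inconclusive"
}
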