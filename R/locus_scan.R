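# Locating precursor homologs in intron sequences and characterising the
# host locus: local alignment hits, per-column conservation of an MSA,
# GC content, CpG islands, and the per-species distribution matrix.
#
# All coordinates are 0-based half-open on the plus strand of the host.

.strip_gaps <- function(x) gsub("[-.]", "", x)

.as_dna_string <- function(x) {
  if (inherits(x, "rna_seq")) x <- x$residues
  x <- toupper(as.character(x))
  x <- chartr("U", "T", x)
  gsub("[^ACGT]", "N", x)
}

#' Locate a precursor homolog in a subject sequence
#'
#' Smith-Waterman local alignment with affine gaps (defaults resemble
#' megablast scoring: match +2, mismatch -3, gap open 5, gap extend 2).
#' The hit is `present` when percent identity and reference coverage both
#' reach their thresholds; the coverage requirement is what keeps short
#' spurious local alignments in unrelated sequence from being called.
#'
#' @param subject Intron (or aligned row; gaps are stripped) as character
#'   or `rna_seq`.
#' @param reference The precursor reference sequence.
#' @param id_threshold Percent identity required for presence.
#' @param cov_threshold Fraction of the reference that must be aligned.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring.
#' @param species Label carried into the hit.
#' @return A `homolog_hit`: species, `interval` (0-based half-open on the
#'   subject), `percent_identity`, `coverage`, `present`, `score`.
#' @export
locate_precursor <- function(subject, reference, id_threshold = 60,
                             cov_threshold = 0.85, match = 2, mismatch = -3,
                             gap_open = 5, gap_ext = 2, species = "") {
  subj <- .as_dna_string(.strip_gaps(
    if (inherits(subject, "rna_seq")) subject$residues else subject))
  ref <- .as_dna_string(
    if (inherits(reference, "rna_seq")) reference$residues else reference)
  if (!nchar(subj) || !nchar(ref)) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = ref, subject = subj, type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_ext)
  aln_len <- nchar(as.character(Biostrings::pattern(al)))
  pid <- if (aln_len > 0L) 100 * Biostrings::nmatch(al) / aln_len else 0
  pr <- Biostrings::pattern(al)
  cov <- (Biostrings::end(pr) - Biostrings::start(pr) + 1L) / nchar(ref)
  sr <- Biostrings::subject(al)
  structure(list(
    species = species,
    interval = c(Biostrings::start(sr) - 1L, Biostrings::end(sr)),
    percent_identity = pid, coverage = cov,
    present = pid >= id_threshold && cov >= cov_threshold,
    score = Biostrings::score(al)), class = "homolog_hit")
}

#' Per-column identity profile of a multiple alignment
#'
#' Identity at a column is the frequency of the modal non-gap residue
#' among the non-gap residues of that column, smoothed by a centred
#' running mean.
#'
#' @param alignment Character vector of equal-length aligned rows (or a
#'   `DNAStringSet`/`RNAStringSet`).
#' @param window Smoothing window (columns); 1 = no smoothing.
#' @return Numeric vector, one value per alignment column (`NaN` for
#'   all-gap columns before smoothing).
#' @export
column_conservation <- function(alignment, window = 1L) {
  if (inherits(alignment, "XStringSet")) alignment <- as.character(alignment)
  stopifnot(is.character(alignment), length(alignment) >= 1L)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("ragged alignment: rows differ in length")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  prof <- apply(m, 2L, function(col) {
    col <- col[!col %in% c("-", ".")]
    if (!length(col)) return(NaN)
    max(table(col)) / length(col)
  })
  if (window > 1L) {
    h <- (as.integer(window) - 1L) %/% 2L
    n <- length(prof)
    prof <- vapply(seq_len(n), function(i) {
      mean(prof[max(1L, i - h):min(n, i + h)], na.rm = TRUE)
    }, numeric(1))
  }
  prof
}

#' GC content of a sequence
#'
#' Fraction (G + C) over counted bases; ambiguity codes are excluded from
#' both numerator and denominator.
#'
#' @param seq Character or `rna_seq` (DNA or RNA).
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content("ACGT")  # 0.5
#' @export
gc_content <- function(seq) {
  x <- .chars(toupper(if (inherits(seq, "rna_seq")) seq$residues else seq))
  counted <- x %in% c("A", "C", "G", "T", "U")
  if (!any(counted)) stop("no countable bases in sequence")
  sum(x %in% c("G", "C")) / sum(counted)
}

#' Observed/expected CpG ratio
#'
#' `(#CpG x N) / (#C x #G)` with `N` the number of counted (unambiguous)
#' bases; 0 when the sequence has no C or no G.
#'
#' @param seq Character or `rna_seq` (DNA frame; U treated as T).
#' @return Non-negative ratio.
#' @examples
#' cpg_obs_exp("CGCG")  # 2
#' @export
cpg_obs_exp <- function(seq) {
  x <- .chars(.as_dna_string(if (inherits(seq, "rna_seq")) seq$residues else seq))
  nC <- sum(x == "C"); nG <- sum(x == "G")
  if (nC == 0L || nG == 0L) return(0)
  ncpg <- sum(x[-length(x)] == "C" & x[-1L] == "G")
  n <- sum(x %in% c("A", "C", "G", "T"))
  ncpg * n / (nC * nG)
}

#' Detect CpG islands
#'
#' Sliding-window scan with the Gardiner-Garden & Frommer criteria
#' (window 200 bp, GC fraction >= 0.5, observed/expected CpG >= 0.6);
#' overlapping passing windows are merged and merged runs shorter than
#' `min_len` dropped. Island boundaries are trimmed to unambiguous bases,
#' which makes calls invariant to flanking poly-N padding.
#'
#' @param seq Character or `rna_seq`.
#' @param min_len,min_gc,min_oe,window,step Detection parameters.
#' @return `data.frame` with `start`, `end` (0-based half-open), `length`,
#'   `gc_fraction`, `obs_exp_cpg`; zero rows (with a warning) when the
#'   sequence is shorter than the window.
#' @export
cpg_islands <- function(seq, min_len = 200L, min_gc = 0.5, min_oe = 0.6,
                        window = 200L, step = 1L) {
  x <- .chars(.as_dna_string(if (inherits(seq, "rna_seq")) seq$residues else seq))
  n <- length(x)
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      gc_fraction = numeric(0), obs_exp_cpg = numeric(0))
  if (n < window) {
    warning("sequence shorter than the scan window; no islands callable")
    return(empty)
  }
  isC <- x == "C"; isG <- x == "G"
  counted <- x %in% c("A", "C", "G", "T")
  isCpG <- c(isC[-n] & isG[-1L], FALSE)
  cC <- c(0L, cumsum(isC)); cG <- c(0L, cumsum(isG))
  cCpG <- c(0L, cumsum(isCpG)); cN <- c(0L, cumsum(counted))
  starts <- seq.int(1L, n - window + 1L, by = step)
  e <- starts + window - 1L
  wC <- cC[e + 1L] - cC[starts]
  wG <- cG[e + 1L] - cG[starts]
  # CpG count within the window (dinucleotide starting inside, ending inside)
  wCpG <- cCpG[e] - cCpG[starts]
  wN <- cN[e + 1L] - cN[starts]
  gc <- ifelse(wN > 0L, (wC + wG) / wN, 0)
  oe <- ifelse(wC > 0L & wG > 0L, wCpG * wN / (wC * wG), 0)
  pass <- gc >= min_gc & oe >= min_oe & wN > 0L
  if (!any(pass)) return(empty)
  ps <- starts[pass]
  grp <- cumsum(c(TRUE, diff(ps) > window))  # merge overlapping/adjacent
  out <- do.call(rbind, lapply(split(ps, grp), function(s) {
    a <- min(s); b <- max(s) + window - 1L   # 1-based inclusive
    idx <- a:b
    inb <- idx[counted[idx]]
    if (!length(inb)) return(NULL)
    a <- min(inb); b <- max(inb)
    if (b - a + 1L < min_len) return(NULL)
    sub <- x[a:b]
    data.frame(start = a - 1L, end = b, length = b - a + 1L,
               gc_fraction = sum(sub %in% c("C", "G")) /
                 sum(sub %in% c("A", "C", "G", "T")),
               obs_exp_cpg = cpg_obs_exp(paste(sub, collapse = "")))
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

.DIST_STATUSES <- c("mirbase_confirmed", "structure_supported",
                    "sequence_predicted", "absent")

#' Per-species distribution matrix of the precursor
#'
#' Combines homolog hits, structural verdicts and external evidence into
#' one status per species, with precedence `mirbase_confirmed` >
#' `structure_supported` > `sequence_predicted` > `absent`.
#' `structure_supported` requires a present hit plus a functional
#' structural verdict. A verdict supplied for a species without a present
#' hit is a consistency error.
#'
#' @param hits Named list of `homolog_hit` (one per species).
#' @param verdicts Named list of `annotation_verdict` for species whose
#'   located candidate was folded and classified (optional).
#' @param mirbase_confirmed Character vector of species with database or
#'   deep-sequencing confirmation.
#' @return `data.frame` with one row per species: `species`, `status`,
#'   `percent_identity`, `coverage`, `mfe`, `main_stem_pairs`.
#' @export
build_distribution_matrix <- function(hits, verdicts = list(),
                                      mirbase_confirmed = character(0)) {
  stopifnot(is.list(hits))
  if (!length(hits)) {
    return(data.frame(species = character(0),
                      status = factor(character(0), levels = .DIST_STATUSES),
                      percent_identity = numeric(0), coverage = numeric(0),
                      mfe = numeric(0), main_stem_pairs = integer(0)))
  }
  stopifnot(!is.null(names(hits)))
  rows <- lapply(names(hits), function(sp) {
    h <- hits[[sp]]
    v <- verdicts[[sp]]
    if (!is.null(v) && !h$present) {
      stop("conflicting evidence for ", sp,
           ": structural verdict supplied but no present hit")
    }
    status <- if (sp %in% mirbase_confirmed) {
      "mirbase_confirmed"
    } else if (h$present && !is.null(v) && v$functional) {
      "structure_supported"
    } else if (h$present) {
      "sequence_predicted"
    } else {
      "absent"
    }
    data.frame(species = sp, status = status,
               percent_identity = h$percent_identity, coverage = h$coverage,
               mfe = if (!is.null(v)) v$measured$mfe else NA_real_,
               main_stem_pairs = if (!is.null(v)) v$measured$main_stem_pairs
                                 else NA_integer_)
  })
  out <- do.call(rbind, rows)
  out$status <- factor(out$status, levels = .DIST_STATUSES)
  rownames(out) <- NULL
  out
}
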