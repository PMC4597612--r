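# Intragenic promoter candidates from CAGE tag starts supported by
# chromatin evidence (DNase I hypersensitivity, H3K4me3, optionally EST
# 5' ends). CAGE tags are clustered by single linkage; clusters upstream
# of (or overlapping) the precursor are flagged by any-overlap with each
# evidence track and ranked.

#' Genomic interval
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (start >= end) stop("invalid interval: start >= end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand), class = "genomic_interval")
}

#' Cluster CAGE tag starts
#'
#' Single-linkage clustering of 5' tag start positions: consecutive
#' positions at most `max_gap` apart join the same cluster; clusters with
#' fewer than `min_tags` total tags are dropped.
#'
#' @param tags `data.frame` with columns `pos` (0-based position) and
#'   `count` (tags at that position, >= 1). Need not be sorted.
#' @param max_gap Maximum gap (bp) between neighbouring tag positions
#'   within one cluster.
#' @param min_tags Minimum total tags to keep a cluster.
#' @return `data.frame` with `start`, `end` (0-based half-open span of the
#'   member positions), `peak_pos` (position with most tags, 5'-most on
#'   ties), `total_tags`, `n_positions`, `width`.
#' @export
cluster_cage <- function(tags, max_gap = 20L, min_tags = 2L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      peak_pos = integer(0), total_tags = integer(0),
                      n_positions = integer(0), width = integer(0))
  if (is.null(tags) || nrow(tags) == 0L) return(empty)
  stopifnot(all(c("pos", "count") %in% names(tags)))
  if (any(tags$count < 1L)) stop("tag counts must be >= 1")
  agg <- stats::aggregate(count ~ pos, data = tags, FUN = sum)
  agg <- agg[order(agg$pos), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(agg$pos) > max_gap))
  out <- do.call(rbind, lapply(split(agg, grp), function(g) {
    data.frame(start = min(g$pos), end = max(g$pos) + 1L,
               peak_pos = g$pos[which.max(g$count)],
               total_tags = sum(g$count), n_positions = nrow(g),
               width = max(g$pos) + 1L - min(g$pos))
  }))
  out <- out[out$total_tags >= min_tags, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.track_overlaps <- function(start, end, track) {
  # any-overlap (>= 1 bp) of [start, end) with any interval of the track
  if (is.null(track) || nrow(track) == 0L) return(FALSE)
  any(track$start < end & track$end > start)
}

.check_chrom <- function(track, chrom, what) {
  if (is.null(track) || nrow(track) == 0L) return(invisible())
  if ("chrom" %in% names(track) && !all(track$chrom == chrom)) {
    stop(what, " track is on a different chromosome than the precursor")
  }
}

#' Nominate promoter candidates for an intragenic miRNA
#'
#' Retains CAGE clusters that overlap the precursor or lie within
#' `search_window` bp upstream of it (strand-aware), flags each by
#' any-overlap with the DNase and H3K4me3 tracks (and an optional EST
#' 5'-end track), and ranks by evidence-flag count (descending), then
#' total tags (descending), then distance to the precursor (ascending).
#' Cluster width is reported rather than clusters being merged, so broad
#' CpG-island-style initiation remains visible.
#'
#' @param clusters Output of [cluster_cage()].
#' @param dnase,h3k4me3,est Evidence tracks as `data.frame`s with `start`,
#'   `end` (0-based half-open; optional `chrom`), or `NULL` when the track
#'   is unavailable (its flag is then `NA` and contributes no evidence).
#' @param premirna A `genomic_interval` for the precursor.
#' @param search_window Upstream search distance in bp.
#' @param locus Optional `genomic_interval`; candidates are restricted to
#'   it.
#' @return `data.frame` of candidates sorted by rank: cluster interval,
#'   `peak_pos`, `total_tags`, `width`, `has_dnase`, `has_h3k4me3`,
#'   `has_est`, `n_evidence`, `distance_to_premirna` (bp, positive =
#'   upstream), `rank`.
#' @export
call_tss_candidates <- function(clusters, dnase = NULL, h3k4me3 = NULL,
                                premirna, search_window = 1000L,
                                est = NULL, locus = NULL) {
  stopifnot(inherits(premirna, "genomic_interval"))
  .check_chrom(dnase, premirna$chrom, "DNase")
  .check_chrom(h3k4me3, premirna$chrom, "H3K4me3")
  .check_chrom(est, premirna$chrom, "EST")
  if (!is.null(locus) && locus$chrom != premirna$chrom) {
    stop("locus is on a different chromosome than the precursor")
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      peak_pos = integer(0), total_tags = integer(0),
                      width = integer(0), has_dnase = logical(0),
                      has_h3k4me3 = logical(0), has_est = logical(0),
                      n_evidence = integer(0),
                      distance_to_premirna = integer(0), rank = integer(0))
  if (is.null(clusters) || nrow(clusters) == 0L) return(empty)
  cl <- clusters
  if (!is.null(locus)) {
    keep <- cl$start < locus$end & cl$end > locus$start
    cl <- cl[keep, , drop = FALSE]
    cl$start <- pmax(cl$start, locus$start)
    cl$end <- pmin(cl$end, locus$end)
  }
  if (nrow(cl) == 0L) return(empty)
  dist <- if (premirna$strand == "+") premirna$start - cl$peak_pos
          else cl$peak_pos - (premirna$end - 1L)
  overlaps_pre <- cl$start < premirna$end & cl$end > premirna$start
  keep <- overlaps_pre | (dist > 0L & dist <= search_window)
  cl <- cl[keep, , drop = FALSE]
  dist <- dist[keep]
  if (nrow(cl) == 0L) return(empty)
  cl$has_dnase <- if (is.null(dnase)) NA else
    mapply(.track_overlaps, cl$start, cl$end, MoreArgs = list(track = dnase))
  cl$has_h3k4me3 <- if (is.null(h3k4me3)) NA else
    mapply(.track_overlaps, cl$start, cl$end, MoreArgs = list(track = h3k4me3))
  cl$has_est <- if (is.null(est)) NA else
    mapply(.track_overlaps, cl$start, cl$end, MoreArgs = list(track = est))
  ev <- cbind(cl$has_dnase, cl$has_h3k4me3, cl$has_est)
  cl$n_evidence <- as.integer(rowSums(ev, na.rm = TRUE))
  cl$distance_to_premirna <- as.integer(dist)
  ord <- order(-cl$n_evidence, -cl$total_tags, abs(cl$distance_to_premirna),
               cl$start)
  cl <- cl[ord, , drop = FALSE]
  cl$rank <- seq_len(nrow(cl))
  cl$n_positions <- NULL
  rownames(cl) <- NULL
  cl
}
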