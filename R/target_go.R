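# Canonical seed-match target discovery, a duplex-stability score, score
# cutoff ranking, and GO-term over-representation of the target set.
#
# The scorer is a documented stand-in for accessibility-based target
# predictors: sites are found by canonical seed rules (8mer, 7mer-m8,
# 7mer-A1, 6mer) and scored by the hybrid duplex energy under an energy
# model; the -20 score cutoff carried from such predictors is a
# configurable default and the scales are not directly comparable.

.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

.revcomp_rna <- function(x) {
  paste(rev(unname(.RNA_COMP[.chars(x)])), collapse = "")
}

#' Find canonical seed-match sites in a 3' UTR
#'
#' The seed is miRNA positions 2-8 (1-based from the 5' end). A site is an
#' occurrence in the UTR (read 5' to 3') of the reverse complement of the
#' 6mer core (positions 2-7); pairing of position 8 and/or an adenosine
#' across from position 1 upgrades it to 7mer-m8, 7mer-A1 or 8mer. Every
#' occurrence is reported (overlapping sites kept), each at its strongest
#' type.
#'
#' @param mirna `rna_seq` or character, at least 8 nt.
#' @param utr UTR sequence (DNA or RNA), character or `rna_seq`.
#' @param utr_id Identifier carried into the results.
#' @return `data.frame` with `utr_id`, `start`, `end` (0-based half-open
#'   site interval on the UTR), `match_type`, and `core_start` (0-based
#'   start of the 6mer core, the register used for scoring).
#' @export
find_seed_matches <- function(mirna, utr, utr_id = "") {
  mirna <- as_rna_seq(mirna)
  if (nchar(mirna$residues) < 8L) stop("miRNA must be at least 8 nt")
  u <- rna_seq(if (inherits(utr, "rna_seq")) utr$residues else utr)$residues
  m <- .chars(mirna$residues)
  core <- .revcomp_rna(paste(m[2:7], collapse = ""))
  m8c <- unname(.RNA_COMP[m[8]])
  uc <- .chars(u)
  n <- length(uc)
  empty <- data.frame(utr_id = character(0), start = integer(0),
                      end = integer(0), match_type = character(0),
                      core_start = integer(0))
  if (n < 6L) return(empty)
  hits <- integer(0)
  corec <- .chars(core)
  for (p in 0:(n - 6L)) {
    if (all(uc[(p + 1L):(p + 6L)] == corec)) hits <- c(hits, p)
  }
  if (!length(hits)) return(empty)
  rows <- lapply(hits, function(p) {
    m8 <- p > 0L && uc[p] == m8c
    a1 <- p + 7L <= n && uc[p + 7L] == "A"
    if (m8 && a1) {
      data.frame(utr_id = utr_id, start = p - 1L, end = p + 7L,
                 match_type = "8mer", core_start = p)
    } else if (m8) {
      data.frame(utr_id = utr_id, start = p - 1L, end = p + 6L,
                 match_type = "7mer-m8", core_start = p)
    } else if (a1) {
      data.frame(utr_id = utr_id, start = p, end = p + 7L,
                 match_type = "7mer-A1", core_start = p)
    } else {
      data.frame(utr_id = utr_id, start = p, end = p + 6L,
                 match_type = "6mer", core_start = p)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# duplex energy of the miRNA hybridised at one site register.
# miRNA position k (1-based) faces UTR position core_start + 7 - k
# (0-based); pairs are WC + GU; under unit_pair each pair scores -1, under
# nearest_neighbor stacking terms are summed over consecutive paired
# positions (a duplex proxy: no loop penalties for interior mismatches).
.site_duplex_energy <- function(mc, uc, core_start, model) {
  n_u <- length(uc)
  ks <- seq_along(mc)
  us <- core_start + 7L - ks  # 0-based
  keep <- us >= 0L & us < n_u
  ks <- ks[keep]; us <- us[keep]
  tb <- uc[us + 1L]
  paired <- .pair_allowed(mc[ks], tb)
  if (model$mode == "unit_pair") return(-1 * sum(paired))
  e <- 0
  st <- model$params$stack
  for (idx in seq_len(length(ks) - 1L)) {
    if (paired[idx] && paired[idx + 1L] && ks[idx + 1L] == ks[idx] + 1L) {
      # closing pair nearer the miRNA 5' end stacks on the next one
      e <- e + st[paste0(mc[ks[idx]], tb[idx]), paste0(mc[ks[idx + 1L]], tb[idx + 1L])]
    }
  }
  e
}

#' Score a UTR against a miRNA over its seed-match sites
#'
#' The UTR score is the minimum (strongest) duplex energy over its sites.
#'
#' @param mirna `rna_seq` or character.
#' @param utr UTR sequence.
#' @param matches Site table from [find_seed_matches()] (must be
#'   non-empty).
#' @param model An `energy_model`.
#' @return A `target_score`: `utr_id`, `best_site` (row of `matches`),
#'   `score` in kcal/mol (more negative = stronger).
#' @export
score_target <- function(mirna, utr, matches, model) {
  if (is.null(matches) || nrow(matches) == 0L) {
    stop("no seed-match sites: score undefined")
  }
  mirna <- as_rna_seq(mirna)
  mc <- .chars(mirna$residues)
  uc <- .chars(rna_seq(if (inherits(utr, "rna_seq")) utr$residues else utr)$residues)
  es <- vapply(matches$core_start, function(p) {
    .site_duplex_energy(mc, uc, p, model)
  }, numeric(1))
  best <- which.min(es)
  structure(list(utr_id = matches$utr_id[best], best_site = matches[best, ],
                 score = es[best]), class = "target_score")
}

#' Retain and rank targets at a score cutoff
#'
#' Retention is inclusive at the cutoff (score <= cutoff). Sorted
#' ascending (strongest first); ties broken stably by `utr_id`.
#'
#' @param scores `data.frame` with `utr_id` and `score`, or a list of
#'   `target_score` objects.
#' @param cutoff Score cutoff (kcal/mol-like scale).
#' @return Filtered, sorted `data.frame`.
#' @export
rank_targets <- function(scores, cutoff = -20.0) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, function(s) {
      data.frame(utr_id = s$utr_id, score = s$score)
    }))
  }
  if (is.null(scores) || nrow(scores) == 0L) {
    return(data.frame(utr_id = character(0), score = numeric(0)))
  }
  stopifnot(all(is.finite(scores$score)))
  out <- scores[scores$score <= cutoff, , drop = FALSE]
  out <- out[order(out$score, out$utr_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GO-term over-representation of a target set
#'
#' Exact hypergeometric upper-tail p per term with Benjamini-Hochberg
#' correction across the tested terms. Terms annotating no background
#' gene are skipped with a warning.
#'
#' @param target_genes Character vector (must be a subset of
#'   `background_genes`).
#' @param background_genes Character vector (non-empty).
#' @param annotations `data.frame` with columns `gene`, `term`.
#' @return `data.frame` sorted by p: `term`, `k_target`, `n_target`,
#'   `k_background`, `n_background`, `fold_enrichment`, `p`, `q`.
#' @export
go_enrichment <- function(target_genes, background_genes, annotations) {
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  if (!length(target_genes)) stop("empty target set")
  if (!length(background_genes)) stop("empty background set")
  if (!all(target_genes %in% background_genes)) {
    stop("target genes must be a subset of the background")
  }
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  ann <- unique(annotations[, c("gene", "term")])
  in_bg <- ann$gene %in% background_genes
  orphan_terms <- setdiff(unique(ann$term), unique(ann$term[in_bg]))
  if (length(orphan_terms)) {
    warning("skipping ", length(orphan_terms),
            " term(s) annotating no background gene")
  }
  ann <- ann[in_bg, , drop = FALSE]
  terms <- sort(unique(ann$term))
  n_t <- length(target_genes)
  n_b <- length(background_genes)
  rows <- lapply(terms, function(tm) {
    genes <- ann$gene[ann$term == tm]
    k_b <- length(unique(genes))
    k_t <- sum(target_genes %in% genes)
    p <- stats::phyper(k_t - 1L, k_b, n_b - k_b, n_t, lower.tail = FALSE)
    data.frame(term = tm, k_target = k_t, n_target = n_t,
               k_background = k_b, n_background = n_b,
               fold_enrichment = (k_t / n_t) / (k_b / n_b), p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
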