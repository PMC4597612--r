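# End-to-end orchestration: the species survey (locate -> fold ->
# classify -> distribution matrix) and the regulation analysis
# (co-expression verdict + promoter candidates). Inputs may be in-memory
# objects or paths to the plain-text formats in io.R; outputs are TSV +
# JSON. Reruns with the same inputs are byte-identical. A failure for one
# species is recorded and the survey continues.

.load_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) read_fasta(x) else x
}

#' Run the species survey
#'
#' For each intron, locates the reference precursor by local alignment;
#' where a hit is present, the matched candidate region is extracted,
#' folded under the energy model, classified against the functional
#' pre-miRNA criteria, and the per-species statuses are combined into a
#' distribution matrix.
#'
#' @param config List with elements: `introns` (named character vector of
#'   intron sequences, or a multi-FASTA path), `reference` (precursor
#'   sequence or single-record FASTA path), optional `model`
#'   (`energy_model`, default unit-pair), `classifier`
#'   (`classifier_config`), `id_threshold`, `cov_threshold`,
#'   `mirbase_confirmed` (species names), `flank` (bp of intron kept
#'   around the hit when folding, default 0), `out_dir`.
#' @return List with `matrix` (distribution `data.frame`), `hits`,
#'   `verdicts`, `folds`, and `errors` (named character of per-species
#'   failures).
#' @export
run_survey <- function(config) {
  introns <- .load_seqs(config$introns)
  if (is.null(introns)) stop("config error: no introns supplied")
  reference <- .load_seqs(config$reference)
  if (!inherits(reference, "rna_seq")) {
    if (is.list(reference) || !is.null(names(reference))) {
      reference <- reference[[1L]]
    }
    reference <- as_rna_seq(reference, id = "reference")
  }
  model <- config$model
  if (is.null(model)) model <- energy_model("unit_pair")
  cfg <- config$classifier
  if (is.null(cfg)) cfg <- classifier_config()
  idt <- if (is.null(config$id_threshold)) 60 else config$id_threshold
  cov <- if (is.null(config$cov_threshold)) 0.85 else config$cov_threshold

  hits <- list(); verdicts <- list(); folds <- list()
  errors <- character(0)
  if (length(introns) == 0L) {
    return(list(matrix = build_distribution_matrix(stats::setNames(list(), character(0))),
                hits = hits, verdicts = verdicts, folds = folds, errors = errors))
  }
  for (sp in names(introns)) {
    res <- tryCatch({
      h <- locate_precursor(introns[[sp]], reference, id_threshold = idt,
                            cov_threshold = cov, species = sp)
      v <- NULL; f <- NULL
      if (h$present) {
        cand <- substr(introns[[sp]], h$interval[1L] + 1L, h$interval[2L])
        sq <- rna_seq(cand, id = sp)
        f <- fold_mfe(sq, model)
        v <- classify(sq, f, arms = NULL, cfg = cfg)
      }
      list(hit = h, verdict = v, fold = f,
           seq = if (h$present) sq else NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[sp] <- conditionMessage(res)
      next
    }
    hits[[sp]] <- res$hit
    if (!is.null(res$verdict)) {
      verdicts[[sp]] <- res$verdict
      folds[[sp]] <- list(seq = res$seq, structure = res$fold)
    }
  }
  mat <- build_distribution_matrix(
    hits, verdicts, mirbase_confirmed = config$mirbase_confirmed %||% character(0))
  if (length(errors)) {
    err_rows <- data.frame(species = names(errors), status = NA,
                           percent_identity = NA_real_, coverage = NA_real_,
                           mfe = NA_real_, main_stem_pairs = NA_integer_)
    mat <- rbind(mat, err_rows)
  }
  out <- list(matrix = mat, hits = hits, verdicts = verdicts, folds = folds,
              errors = errors)
  if (!is.null(config$out_dir)) .write_survey(out, config$out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_survey <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(out$matrix, file.path(dir, "distribution_matrix.tsv"))
  if (length(out$hits)) {
    bed <- do.call(rbind, lapply(out$hits, function(h) {
      data.frame(chrom = h$species, start = h$interval[1L],
                 end = h$interval[2L], name = "precursor_hit",
                 score = round(h$score), strand = "+")
    }))
    write_bed(bed, file.path(dir, "hits.bed"))
  }
  if (length(out$verdicts)) {
    vt <- do.call(rbind, lapply(names(out$verdicts), function(sp) {
      v <- out$verdicts[[sp]]
      data.frame(species = sp, functional = v$functional,
                 energy_ok = v$energy_ok, stem_ok = v$stem_ok,
                 mature_ok = v$mature_ok, hairpin_ok = v$hairpin_ok,
                 mfe = v$measured$mfe,
                 main_stem_pairs = v$measured$main_stem_pairs,
                 largest_mature_defect = v$measured$largest_mature_defect)
    }))
    write_tsv(vt, file.path(dir, "verdicts.tsv"))
    write_vienna(unname(out$folds), file.path(dir, "folds.vienna"))
  }
  invisible(dir)
}

#' Run the regulation analysis
#'
#' Combines the host/miRNA co-expression verdict with ranked intragenic
#' promoter candidates. A missing evidence track is reported as an
#' unavailable flag (`NA`), never fabricated.
#'
#' @param config List with elements: `expression` (`data.frame` with
#'   `mirna` and `host` call columns, or a TSV path with row names),
#'   `tags` (CAGE `data.frame` pos/count or TSV path), `dnase`,
#'   `h3k4me3`, `est` (BED-like `data.frame`s, BED paths, or `NULL`),
#'   `premirna` (`genomic_interval`), optional `locus`, `search_window`,
#'   `max_gap`, `min_tags`, `out_dir`.
#' @return List with `coexpression` (`coexpression_table`), `verdict`
#'   (transcription-mode call), and `candidates` (ranked TSS table).
#' @export
run_regulation <- function(config) {
  expr <- config$expression
  if (is.character(expr) && length(expr) == 1L) expr <- read_tsv(expr, row_names = TRUE)
  verdict <- NULL; tab <- NULL
  if (!is.null(expr) && nrow(expr) > 0L) {
    tab <- coexpression_table(expr$mirna, expr$host)
    verdict <- infer_transcription_modes(tab)
  } else {
    verdict <- "inconclusive"
    tab <- structure(list(both = 0L, mirna_only = 0L, host_only = 0L,
                          neither = 0L, n = 0L), class = "coexpression_table")
  }
  load_track <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) read_bed(x) else x
  }
  tags <- config$tags
  if (is.character(tags) && length(tags) == 1L && file.exists(tags)) {
    tags <- read_tsv(tags)
  }
  candidates <- NULL
  if (!is.null(tags) && !is.null(config$premirna)) {
    cl <- cluster_cage(tags, max_gap = config$max_gap %||% 20L,
                       min_tags = config$min_tags %||% 2L)
    candidates <- call_tss_candidates(
      cl, dnase = load_track(config$dnase),
      h3k4me3 = load_track(config$h3k4me3),
      premirna = config$premirna,
      search_window = config$search_window %||% 1000L,
      est = load_track(config$est), locus = config$locus)
  }
  out <- list(coexpression = tab, verdict = verdict, candidates = candidates)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(verdict = verdict,
           coexpression = tab[c("both", "mirna_only", "host_only", "neither")]),
      file.path(config$out_dir, "regulation_summary.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(candidates)) {
      write_tsv(candidates, file.path(config$out_dir, "tss_candidates.tsv"))
    }
  }
  out
}
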