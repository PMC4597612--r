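# Deterministic generators for every input the pipeline consumes, with
# known ground truth: precursors with planted stem/defect layouts,
# degraded variants, intron embeddings, arm-biased small-RNA read sets,
# promoter evidence tracks with planted TSSs, and two-promoter expression
# matrices.
#
# Precursor construction uses a constrained alphabet: stem pairs are G:C
# with the whole 5' side G and 3' side C, and every unpaired region
# (hairpin loop, bulges, internal loops) is A. The sequence then contains
# no U, so the only possible pairs are the planted G:C ones, and the only
# non-crossing perfect matching between the G block and the C block is the
# planted one: the unit-model MFE structure provably equals the planted
# layout exactly. Generators are fully deterministic under (arguments,
# seed); one run seed fans out to per-generator subseeds via a fixed
# counter scheme.

#' Derive a per-generator subseed from a run seed
#'
#' @param seed Integer run seed.
#' @param idx Generator counter.
#' @return Integer below 2^31.
#' @export
subseed <- function(seed, idx) {
  (abs(as.integer(seed)) + 7919L * as.integer(idx)) %% .Machine$integer.max
}

#' Build a precursor with a planted stem-loop layout
#'
#' @param stem_pairs Pairs on the main stem (>= 1).
#' @param loop_len Hairpin loop length (>= 3).
#' @param defects List of planted defects, each
#'   `list(type = "internal"|"bulge", at = k, size5 =, size3 =)` inserted
#'   after the k-th stem pair counted from the outside (`1 <= k <
#'   stem_pairs`); for a bulge exactly one side size is zero.
#' @return List with `seq` (`rna_seq`), `structure` (`rna_structure`,
#'   unit-model energy `-stem_pairs`), `arms` (`mature_arms`, 22 nt
#'   abutting the loop).
#' @export
make_precursor <- function(stem_pairs = 22L, loop_len = 4L, defects = list()) {
  stem_pairs <- as.integer(stem_pairs); loop_len <- as.integer(loop_len)
  if (stem_pairs < 1L) stop("stem_pairs must be >= 1")
  if (loop_len < 3L) stop("loop_len must be >= 3")
  for (d in defects) {
    if (!d$type %in% c("internal", "bulge")) stop("unknown defect type")
    if (d$at < 1L || d$at >= stem_pairs) {
      stop("defect position exceeds the stem")
    }
    if (d$type == "bulge" && (d$size5 > 0L) == (d$size3 > 0L)) {
      stop("a bulge must have exactly one non-empty side")
    }
  }
  left <- right <- ldb <- rdb <- character(0)
  for (k in seq_len(stem_pairs)) {
    left <- c(left, "G"); ldb <- c(ldb, "(")
    right <- c("C", right); rdb <- c(")", rdb)
    for (d in defects) {
      if (d$at == k) {
        if (d$size5 > 0L) {
          left <- c(left, rep("A", d$size5)); ldb <- c(ldb, rep(".", d$size5))
        }
        if (d$size3 > 0L) {
          right <- c(rep("A", d$size3), right); rdb <- c(rep(".", d$size3), rdb)
        }
      }
    }
  }
  residues <- paste(c(left, rep("A", loop_len), right), collapse = "")
  db <- paste(c(ldb, rep(".", loop_len), rdb), collapse = "")
  st <- rna_structure(db, energy = -stem_pairs)
  list(seq = rna_seq(residues, id = "synthetic_precursor"),
       structure = st, arms = default_arms(st))
}

#' Degrade a precursor by random substitutions
#'
#' Models structural decay of an unselected hairpin: `n_mutations`
#' positions are sampled without replacement and substituted with a
#' different random base.
#'
#' @param precursor `rna_seq` or character.
#' @param n_mutations Number of substitutions (<= length).
#' @param seed Integer seed.
#' @param positions Optional pool of 1-based positions to mutate within
#'   (defaults to the whole sequence).
#' @param mode `"random"` substitutes with a uniformly chosen different
#'   base; `"loop_opening"` substitutes toward `A` (the least
#'   pairing-prone base), modelling mutations that open pairs rather than
#'   re-pair.
#' @param spread When `TRUE`, mutated positions are drawn one per
#'   equal-width bin of the position pool instead of uniformly, so
#'   substitutions cannot cluster.
#' @return An `rna_seq`.
#' @export
degrade_precursor <- function(precursor, n_mutations, seed, positions = NULL,
                              mode = c("random", "loop_opening"),
                              spread = FALSE) {
  mode <- match.arg(mode)
  precursor <- as_rna_seq(precursor)
  x <- .chars(precursor$residues)
  n_mutations <- as.integer(n_mutations)
  if (n_mutations > length(x)) stop("more mutations than positions")
  if (n_mutations == 0L) return(precursor)
  if (is.null(positions)) positions <- seq_along(x)
  if (n_mutations > length(positions)) stop("more mutations than positions")
  set.seed(seed)
  mut <- if (spread) {
    bins <- split(positions, cut(seq_along(positions), n_mutations,
                                 labels = FALSE))
    vapply(bins, function(b) b[sample.int(length(b), 1L)], numeric(1))
  } else {
    sample(positions, n_mutations)
  }
  for (i in mut) {
    x[i] <- if (mode == "loop_opening") {
      if (x[i] == "A") "C" else "A"
    } else {
      sample(setdiff(c("A", "C", "G", "U"), x[i]), 1L)
    }
  }
  rna_seq(paste(x, collapse = ""), id = paste0(precursor$id, "_degraded"))
}

#' Embed a precursor verbatim in a synthetic intron
#'
#' The background has an exact GC fraction (`round(gc_target * n)` G/C
#' bases, shuffled) and the precursor is inserted at a seeded position.
#'
#' @param precursor `rna_seq`, character, or `NULL` for a background-only
#'   intron.
#' @param intron_len Total intron length.
#' @param gc_target Background GC fraction.
#' @param seed Integer seed.
#' @return List with `intron` (DNA character), `interval` (0-based
#'   half-open location of the insert, or `NULL`).
#' @export
embed_in_intron <- function(precursor, intron_len = 2000L, gc_target = 0.5,
                            seed = 1L) {
  set.seed(seed)
  pre <- if (is.null(precursor)) "" else
    chartr("U", "T", as_rna_seq(precursor)$residues)
  plen <- nchar(pre)
  bg_len <- as.integer(intron_len) - plen
  if (bg_len < 0L) stop("intron shorter than the precursor")
  ngc <- round(gc_target * bg_len)
  bases <- c(sample(c("G", "C"), ngc, replace = TRUE),
             sample(c("A", "T"), bg_len - ngc, replace = TRUE))
  bases <- sample(bases)
  if (plen == 0L) {
    return(list(intron = paste(bases, collapse = ""), interval = NULL))
  }
  at <- sample.int(bg_len + 1L, 1L) - 1L  # 0-based insert offset
  after <- if (at < bg_len) bases[(at + 1L):bg_len] else character(0)
  intron <- paste(c(bases[seq_len(at)], .chars(pre), after), collapse = "")
  list(intron = intron, interval = c(at, at + plen))
}

#' Simulate arm-biased small-RNA reads
#'
#' Arm of origin is Bernoulli with probability `dominance` for the 3p arm;
#' read lengths are uniform on 20-24 nt (clipped to the arm); per-base
#' substitution errors occur at rate `error_rate` (substitutions only).
#'
#' @param precursor `rna_seq` or character.
#' @param arms A `mature_arms`.
#' @param depth Number of reads.
#' @param dominance True 3p fraction.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return List with `reads` (character vector) and `truth`
#'   (`data.frame` of arm, start, length per read).
#' @export
simulate_reads <- function(precursor, arms, depth, dominance,
                           error_rate = 0, seed = 1L) {
  precursor <- as_rna_seq(precursor)
  x <- .chars(precursor$residues)
  set.seed(seed)
  depth <- as.integer(depth)
  if (depth == 0L) {
    return(list(reads = character(0),
                truth = data.frame(arm = character(0), start = integer(0),
                                   length = integer(0))))
  }
  arm3 <- stats::runif(depth) < dominance
  reads <- character(depth)
  truth <- data.frame(arm = ifelse(arm3, "3p", "5p"), start = integer(depth),
                      length = integer(depth))
  for (i in seq_len(depth)) {
    iv <- if (arm3[i]) arms$arm3p else arms$arm5p
    w <- iv[2L] - iv[1L]
    len <- min(sample(20:24, 1L), w)
    s <- iv[1L] + sample.int(w - len + 1L, 1L) - 1L  # 0-based
    rd <- x[(s + 1L):(s + len)]
    if (error_rate > 0) {
      err <- stats::runif(len) < error_rate
      for (j in which(err)) rd[j] <- sample(setdiff(c("A", "C", "G", "U"), rd[j]), 1L)
    }
    reads[i] <- paste(rd, collapse = "")
    truth$start[i] <- s; truth$length[i] <- len
  }
  list(reads = reads, truth = truth)
}

#' Simulate promoter evidence tracks with planted TSSs
#'
#' Tag counts at each planted TSS are Poisson(`tag_depth`) with +/- 5 bp
#' positional jitter per tag; `noise_tags` single-count tags fall
#' uniformly over the region. DNase and H3K4me3 peaks are placed over each
#' planted TSS.
#'
#' @param tss_positions Integer vector of planted TSS positions (0-based).
#' @param tag_depth Expected tags per planted TSS.
#' @param noise_tags Number of uniform background tags.
#' @param region `c(start, end)` of the simulated locus (0-based
#'   half-open).
#' @param peak_halfwidth Half-width (bp) of the evidence peaks.
#' @param chrom Chromosome label used on the tracks.
#' @param seed Integer seed.
#' @return List with `tags` (`data.frame` pos/count), `dnase`, `h3k4me3`
#'   (BED-like `data.frame`s), and `truth` (the planted positions).
#' @export
simulate_locus_tracks <- function(tss_positions, tag_depth = 50L,
                                  noise_tags = 0L, region,
                                  peak_halfwidth = 150L, chrom = "chrS",
                                  seed = 1L) {
  set.seed(seed)
  pos <- integer(0)
  for (tss in tss_positions) {
    n <- stats::rpois(1L, tag_depth)
    if (n > 0L) pos <- c(pos, tss + sample(-5:5, n, replace = TRUE))
  }
  if (noise_tags > 0L) {
    pos <- c(pos, region[1L] + sample.int(region[2L] - region[1L],
                                          noise_tags, replace = TRUE) - 1L)
  }
  pos <- pmin(pmax(pos, region[1L]), region[2L] - 1L)
  tags <- if (length(pos)) {
    tb <- table(pos)
    data.frame(pos = as.integer(names(tb)), count = as.integer(tb))
  } else data.frame(pos = integer(0), count = integer(0))
  peaks <- if (length(tss_positions)) {
    data.frame(chrom = chrom,
               start = pmax(region[1L], tss_positions - peak_halfwidth),
               end = pmin(region[2L], tss_positions + peak_halfwidth))
  } else data.frame(chrom = character(0), start = integer(0), end = integer(0))
  list(tags = tags, dnase = peaks, h3k4me3 = peaks,
       truth = list(tss_positions = tss_positions))
}

#' Simulate a two-promoter expression call matrix
#'
#' The host gene is present with probability `p_host_on`; the miRNA is
#' present whenever the host is, and additionally with probability
#' `p_mirna_only` when the host is absent. By construction there are no
#' host-only samples.
#'
#' @param n_samples Number of samples (> 0).
#' @param p_host_on,p_mirna_only Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return `data.frame` with columns `mirna` and `host`
#'   (`present`/`absent`), one row per sample.
#' @export
simulate_expression_matrix <- function(n_samples, p_host_on, p_mirna_only,
                                       seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (n_samples <= 0L) stop("n_samples must be positive")
  stopifnot(p_host_on >= 0, p_host_on <= 1, p_mirna_only >= 0, p_mirna_only <= 1)
  set.seed(seed)
  host <- stats::runif(n_samples) < p_host_on
  mirna <- host | (stats::runif(n_samples) < p_mirna_only)
  out <- data.frame(mirna = ifelse(mirna, "present", "absent"),
                    host = ifelse(host, "present", "absent"))
  rownames(out) <- sprintf("sample_%02d", seq_len(n_samples))
  out
}

#' Simulate a clade of host introns around a reference precursor
#'
#' Plants three species classes mirroring a presence/degradation/loss
#' survey: `n_functional` introns carry the reference precursor verbatim,
#' `n_degraded` carry a mutated copy (recognisable by sequence but
#' structurally broken), and `n_absent` carry no insert.
#'
#' @param n_functional,n_degraded,n_absent Species counts per class.
#' @param stem_pairs,loop_len Precursor layout.
#' @param n_mutations Substitutions applied to degraded copies.
#' @param intron_len,gc_target Intron background parameters.
#' @param seed Integer run seed (fans out per species via [subseed()]).
#' @return List with `reference` (the precursor `rna_seq`), `arms`,
#'   `introns` (named character vector of intron DNA), and `truth`
#'   (`data.frame` species, class, insert start/end).
#' @export
simulate_clade <- function(n_functional = 6L, n_degraded = 2L, n_absent = 1L,
                           stem_pairs = 22L, loop_len = 4L,
                           n_mutations = 14L, intron_len = 2000L,
                           gc_target = 0.5, seed = 1L) {
  pre <- make_precursor(stem_pairs, loop_len)
  classes <- rep(c("functional", "degraded", "absent"),
                 c(n_functional, n_degraded, n_absent))
  species <- sprintf("%s_%02d", classes,
                     as.integer(stats::ave(seq_along(classes), classes,
                                           FUN = seq_along)))
  introns <- character(0)
  truth <- data.frame(species = species, class = classes,
                      insert_start = NA_integer_, insert_end = NA_integer_)
  plen <- nchar(pre$seq$residues)
  for (i in seq_along(species)) {
    ins <- switch(classes[i],
      functional = pre$seq,
      degraded = degrade_precursor(pre$seq, n_mutations,
                                   seed = subseed(seed, 100L + i),
                                   positions = 5:(plen - 4L),
                                   mode = "loop_opening", spread = TRUE),
      absent = NULL)
    emb <- embed_in_intron(ins, intron_len, gc_target,
                           seed = subseed(seed, 200L + i))
    introns[species[i]] <- emb$intron
    if (!is.null(emb$interval)) {
      truth$insert_start[i] <- emb$interval[1L]
      truth$insert_end[i] <- emb$interval[2L]
    }
  }
  list(reference = pre$seq, arms = pre$arms, structure = pre$structure,
       introns = introns, truth = truth)
}

#' Write a complete synthetic study to disk
#'
#' Emits every input the pipeline consumes (intron FASTA, reads FASTA,
#' expression matrix TSV, CAGE bedGraph-like TSV, DNase/H3K4me3 BED) plus
#' a `truth.json` sidecar holding each generator's ground truth.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer run seed.
#' @param n_samples Expression-matrix samples.
#' @param p_host_on,p_mirna_only Expression-model probabilities.
#' @param read_depth,dominance Read-set parameters.
#' @param tss_offset Planted intragenic TSS distance upstream of the
#'   precursor (bp).
#' @param ... Passed to [simulate_clade()].
#' @return Invisibly, the list of generated objects.
#' @export
simulate_study <- function(dir, seed = 1L, n_samples = 40L, p_host_on = 0.3,
                           p_mirna_only = 0.5, read_depth = 1000L,
                           dominance = 0.8, tss_offset = 550L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clade <- simulate_clade(seed = seed, ...)
  reads <- simulate_reads(clade$reference, clade$arms, read_depth, dominance,
                          seed = subseed(seed, 1L))
  expr <- simulate_expression_matrix(n_samples, p_host_on, p_mirna_only,
                                     seed = subseed(seed, 2L))
  pre_start <- 5000L
  plen <- nchar(clade$reference$residues)
  tracks <- simulate_locus_tracks(
    tss_positions = pre_start - tss_offset, tag_depth = 50L,
    noise_tags = 200L, region = c(0L, 10000L), seed = subseed(seed, 3L))
  premirna <- genomic_interval("chrS", pre_start, pre_start + plen, "+")

  write_fasta(clade$introns, file.path(dir, "introns.fasta"))
  write_fasta(stats::setNames(chartr("U", "T", clade$reference$residues),
                              "reference_precursor"),
              file.path(dir, "reference.fasta"))
  write_fasta(stats::setNames(reads$reads,
                              sprintf("read_%04d", seq_along(reads$reads))),
              file.path(dir, "reads.fasta"))
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(tracks$tags, file.path(dir, "cage_tags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(tracks$dnase, file.path(dir, "dnase.bed"))
  write_bed(tracks$h3k4me3, file.path(dir, "h3k4me3.bed"))
  truth <- list(seed = seed, clade = clade$truth,
                arms = list(arm5p = clade$arms$arm5p, arm3p = clade$arms$arm3p),
                dominance = dominance,
                read_truth_3p = sum(reads$truth$arm == "3p"),
                expression = list(p_host_on = p_host_on,
                                  p_mirna_only = p_mirna_only),
                tss = tracks$truth$tss_positions,
                premirna = c(premirna$start, premirna$end))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(clade = clade, reads = reads, expression = expr,
                 tracks = tracks, premirna = premirna, truth = truth))
}
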