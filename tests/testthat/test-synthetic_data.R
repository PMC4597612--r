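# Generators: planted ground truth, determinism, and recovery by the
# analysis operations.

test_that("constructed precursors fold to exactly the planted layout", {
  m <- energy_model("unit_pair")
  pre <- make_precursor(22L, 4L)
  f <- fold_mfe(pre$seq, m)
  expect_identical(f$dotbracket, pre$structure$dotbracket)
  expect_equal(f$energy, -22)
  expect_true(classify(pre$seq, f)$functional)
  # with planted defects the unique maximum pairing is still the layout
  pre2 <- make_precursor(20L, 5L, defects = list(
    list(type = "bulge", at = 6L, size5 = 3L, size3 = 0L),
    list(type = "internal", at = 14L, size5 = 2L, size3 = 2L)))
  f2 <- fold_mfe(pre2$seq, m)
  expect_identical(f2$dotbracket, pre2$structure$dotbracket)
  # planted 8-nt internal loop in the 3p arm fails the mature criterion
  pre3 <- make_precursor(22L, 4L, defects = list(
    list(type = "internal", at = 12L, size5 = 1L, size3 = 8L)))
  v <- classify(pre3$seq, fold_mfe(pre3$seq, m), arms = pre3$arms)
  expect_false(v$mature_ok)
})

test_that("recipe validation rejects impossible layouts", {
  expect_error(make_precursor(0L), "stem_pairs")
  expect_error(make_precursor(10L, 2L), "loop_len")
  expect_error(make_precursor(10L, 4L, defects = list(
    list(type = "internal", at = 10L, size5 = 2L, size3 = 2L))), "exceeds")
  expect_error(make_precursor(10L, 4L, defects = list(
    list(type = "bulge", at = 3L, size5 = 2L, size3 = 2L))), "one non-empty")
})

test_that("degradation is seeded, reproducible and bounded", {
  pre <- make_precursor(18L, 4L)
  expect_identical(degrade_precursor(pre$seq, 0L, seed = 1)$residues,
                   pre$seq$residues)
  d1 <- degrade_precursor(pre$seq, 10L, seed = 5)
  d2 <- degrade_precursor(pre$seq, 10L, seed = 5)
  expect_identical(d1$residues, d2$residues)
  expect_false(identical(degrade_precursor(pre$seq, 10L, seed = 6)$residues,
                         d1$residues))
  n_diff <- sum(strsplit(d1$residues, "")[[1]] !=
                  strsplit(pre$seq$residues, "")[[1]])
  expect_equal(n_diff, 10L)
  expect_error(degrade_precursor(pre$seq, 1000L, seed = 1), "more mutations")
})

test_that("intron embedding hits the GC target and is recoverable", {
  pre <- make_precursor(22L, 4L)
  for (s in 1:5) {
    emb <- embed_in_intron(pre$seq, 2000L, 0.4, seed = s)
    iv <- emb$interval
    bg <- paste0(substr(emb$intron, 1, iv[1]),
                 substr(emb$intron, iv[2] + 1, nchar(emb$intron)))
    expect_lt(abs(gc_content(bg) - 0.4), 0.02)
    expect_identical(substr(emb$intron, iv[1] + 1, iv[2]),
                     chartr("U", "T", pre$seq$residues))
    h <- locate_precursor(emb$intron, pre$seq)
    expect_equal(h$interval, iv)
  }
  # zero-length flank allowed
  emb0 <- embed_in_intron(pre$seq, nchar(pre$seq$residues), 0.5, seed = 1)
  expect_equal(emb0$interval, c(0L, nchar(pre$seq$residues)))
  expect_error(embed_in_intron(pre$seq, 10L, 0.5, seed = 1), "shorter")
})

test_that("read simulation honours depth, dominance and determinism", {
  pre <- make_precursor(22L, 4L)
  expect_length(simulate_reads(pre$seq, pre$arms, 0L, 0.8, seed = 1)$reads, 0L)
  r1 <- simulate_reads(pre$seq, pre$arms, 50L, 0.8, seed = 2)
  r2 <- simulate_reads(pre$seq, pre$arms, 50L, 0.8, seed = 2)
  expect_identical(r1, r2)
  expect_true(all(nchar(r1$reads) >= 20L & nchar(r1$reads) <= 24L))
  # estimated dominance within the exact binomial 99% interval of truth
  rs <- simulate_reads(pre$seq, pre$arms, 1000L, 0.8, seed = 3)
  est <- arm_dominance(count_arm_reads(rs$reads, pre$seq, pre$arms))
  ci <- stats::qbinom(c(0.005, 0.995), 1000L, 0.8) / 1000
  expect_gte(est, ci[1])
  expect_lte(est, ci[2])
})

test_that("track simulation plants recoverable TSS evidence", {
  # no noise, one TSS: a single cluster at the planted position
  tr <- simulate_locus_tracks(3000L, tag_depth = 30L, noise_tags = 0L,
                              region = c(0L, 8000L), seed = 4)
  cl <- cluster_cage(tr$tags)
  expect_equal(nrow(cl), 1L)
  expect_lte(abs(cl$peak_pos - 3000L), 5L)
  expect_gte(nrow(tr$dnase), 1L)  # peaks emitted
  expect_identical(simulate_locus_tracks(3000L, 30L, 100L, c(0L, 8000L),
                                         seed = 9),
                   simulate_locus_tracks(3000L, 30L, 100L, c(0L, 8000L),
                                         seed = 9))
})

test_that("expression matrices encode the two-promoter model", {
  m0 <- simulate_expression_matrix(40L, 0.3, 0, seed = 1)
  expect_equal(infer_transcription_modes(coexpression_table(m0$mirna, m0$host)),
               "host_coupled_only")
  m1 <- simulate_expression_matrix(40L, 0.3, 0.5, seed = 1)
  tab <- coexpression_table(m1$mirna, m1$host)
  expect_equal(tab$host_only, 0L)  # impossible by construction
  expect_error(simulate_expression_matrix(0L, 0.5, 0.5, seed = 1), "positive")
})

test_that("a written study round-trips through the file formats", {
  dir <- tempfile("study")
  st <- simulate_study(dir, seed = 123L)
  expect_true(all(file.exists(file.path(
    dir, c("introns.fasta", "reference.fasta", "reads.fasta",
           "expression.tsv", "cage_tags.tsv", "dnase.bed", "h3k4me3.bed",
           "truth.json")))))
  introns <- read_fasta(file.path(dir, "introns.fasta"))
  expect_identical(introns, st$clade$introns)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 123L)
  expect_equal(nrow(truth$clade), nrow(st$clade$truth))
  expr <- read_tsv(file.path(dir, "expression.tsv"), row_names = TRUE)
  expect_equal(expr$mirna, st$expression$mirna)
  bed <- read_bed(file.path(dir, "dnase.bed"))
  expect_equal(bed$start, st$tracks$dnase$start)
  unlink(dir, recursive = TRUE)
})
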