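# Homolog location, conservation profiles, GC/CpG statistics and the
# distribution matrix.

test_that("a verbatim insert is recovered exactly", {
  set.seed(3)
  pre <- make_precursor(22L, 4L)
  emb <- embed_in_intron(pre$seq, 2000L, 0.5, seed = 4)
  h <- locate_precursor(emb$intron, pre$seq, species = "sp1")
  expect_true(h$present)
  expect_equal(h$percent_identity, 100)
  expect_equal(h$coverage, 1)
  expect_equal(h$interval, emb$interval)
})

test_that("10% substitution still yields a present hit; background does not", {
  set.seed(17)
  for (r in 1:10) {
    ref <- random_rna(60)
    mut <- degrade_precursor(ref, 6L, seed = r, spread = TRUE)
    emb <- embed_in_intron(mut, 2000L, 0.5, seed = r + 50)
    h <- locate_precursor(emb$intron, ref)
    expect_gte(h$percent_identity, 80)
    expect_true(h$present)
    # background-only intron of the same composition: no present call
    emb0 <- embed_in_intron(NULL, 2000L, 0.5, seed = r + 100)
    expect_false(locate_precursor(emb0$intron, ref)$present)
  }
})

test_that("alignment score is symmetric under reverse-complementing both", {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  set.seed(23)
  for (r in 1:5) {
    ref <- random_rna(40)
    emb <- embed_in_intron(degrade_precursor(ref, 4L, seed = r), 500L, 0.5,
                           seed = r)
    h1 <- locate_precursor(emb$intron, ref)
    h2 <- locate_precursor(rc(emb$intron), rc(chartr("U", "T", ref)))
    expect_equal(h1$score, h2$score)
  }
})

test_that("column conservation matches the definition and generator truth", {
  expect_equal(column_conservation(c("ACGT", "ACGT")), c(1, 1, 1, 1))
  expect_equal(column_conservation(c("ACGT", "ACGA")), c(1, 1, 1, 0.5))
  expect_error(column_conservation(c("ACGT", "ACG")), "ragged")
  # gaps excluded from the column denominator
  expect_equal(column_conservation(c("A-", "AC", "AC")), c(1, 1))
  # conserved core flanked by random columns
  set.seed(41)
  core <- random_rna(40)
  rows <- vapply(1:6, function(i) {
    paste0(random_rna(30), core, random_rna(30))
  }, character(1))
  prof <- column_conservation(rows, window = 5L)
  expect_gt(mean(prof[31:70]), mean(prof[c(1:30, 71:100)]))
})

test_that("gc_content follows its definition and swap symmetry", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("ACGTNNN"), 0.5)  # ambiguity excluded
  expect_error(gc_content("NNN"), "no countable")
  set.seed(53)
  for (r in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    swapped <- chartr("ACGT", "GTAC", s)  # A<->G, C<->T swaps AT<->GC class
    expect_equal(gc_content(s), 1 - gc_content(swapped))
  }
})

test_that("CpG observed/expected ratio is exact", {
  expect_equal(cpg_obs_exp("CGCG"), 2)
  expect_equal(cpg_obs_exp("AAAA"), 0)
  expect_equal(cpg_obs_exp("CCGG"), 1 * 4 / (2 * 2))
})

test_that("CpG islands find a planted GC-rich insert and ignore noise", {
  set.seed(67)
  at_bg <- function(n) paste(sample(c("A", "T"), n, TRUE), collapse = "")
  insert <- paste(sample(c("C", "G", "A", "T"), 300, TRUE,
                         prob = c(0.35, 0.35, 0.15, 0.15)), collapse = "")
  s <- paste0(at_bg(500), insert, at_bg(500))
  isl <- cpg_islands(s)
  expect_equal(nrow(isl), 1L)
  covered <- min(isl$end[1], 800L) - max(isl$start[1], 500L)
  expect_gte(covered / 300, 0.8)
  expect_gte(isl$gc_fraction[1], 0.5)
  expect_gte(isl$obs_exp_cpg[1], 0.6)
  # poly-A gives nothing; short input warns and returns empty
  expect_equal(nrow(cpg_islands(strrep("A", 500))), 0L)
  expect_warning(out <- cpg_islands("ACGT"), "shorter")
  expect_equal(nrow(out), 0L)
  # flanking poly-N padding shifts but does not change the calls
  pad <- strrep("N", 300)
  isl_n <- cpg_islands(paste0(pad, s, pad))
  expect_equal(isl_n$start, isl$start + 300L)
  expect_equal(isl_n$end, isl$end + 300L)
  expect_equal(isl_n$gc_fraction, isl$gc_fraction)
})

test_that("distribution matrix applies status precedence and consistency", {
  hit <- function(present) structure(
    list(species = "x", interval = c(0L, 10L), percent_identity = 99,
         coverage = 1, present = present, score = 50), class = "homolog_hit")
  verdict <- function(fun) structure(
    list(functional = fun,
         measured = list(mfe = -22, main_stem_pairs = 22L)),
    class = "annotation_verdict")
  m <- build_distribution_matrix(
    list(a = hit(TRUE), b = hit(TRUE), c = hit(FALSE), d = hit(TRUE)),
    verdicts = list(a = verdict(TRUE), b = verdict(FALSE), d = verdict(TRUE)),
    mirbase_confirmed = "d")
  expect_equal(as.character(m$status[m$species == "a"]), "structure_supported")
  expect_equal(as.character(m$status[m$species == "b"]), "sequence_predicted")
  expect_equal(as.character(m$status[m$species == "c"]), "absent")
  expect_equal(as.character(m$status[m$species == "d"]), "mirbase_confirmed")
  expect_error(
    build_distribution_matrix(list(x = hit(FALSE)),
                              verdicts = list(x = verdict(TRUE))),
    "conflicting")
})
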