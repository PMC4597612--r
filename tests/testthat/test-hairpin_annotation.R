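# Stem-loop decomposition and the four-criterion classifier.

test_that("decompose handles canonical hairpins", {
  d <- decompose("((((....))))")
  expect_true(d$is_simple_hairpin)
  expect_equal(d$main_stem_pairs, 4L)
  expect_equal(d$elements[[1]]$paired_count, 4L)
  expect_equal(d$elements[[2]]$type, "hairpin_loop")
  expect_equal(d$elements[[2]]$size, 4L)

  d2 <- decompose("(((..(((...)))..)))")
  expect_identical(vapply(d2$elements, `[[`, "", "type"),
                   c("helix", "internal_loop", "helix", "hairpin_loop"))
  expect_equal(d2$main_stem_pairs, 6L)
  expect_equal(d2$elements[[2]]$size5, 2L)
  expect_equal(d2$elements[[2]]$size3, 2L)

  expect_error(decompose("((..((...)))"), "unbalanced")
  expect_false(decompose("((...(((...)))..(((...))).))")$is_simple_hairpin)
  expect_false(decompose("......")$is_simple_hairpin)
})

.stem_structure <- function(pairs, loop = 4L, energy = -30) {
  db <- paste0(strrep("(", pairs), strrep(".", loop), strrep(")", pairs))
  sq <- paste0(strrep("G", pairs), strrep("A", loop), strrep("C", pairs))
  list(seq = sq, structure = rna_structure(db, energy = energy))
}

test_that("each criterion flips independently at its boundary", {
  base <- .stem_structure(22L)
  # energy boundary is strict at the threshold
  for (e in c(-17.99, -18, -18.01)) {
    v <- classify(base$seq, rna_structure(base$structure$dotbracket, e))
    expect_equal(v$energy_ok, e < -18)
    expect_true(v$stem_ok && v$mature_ok && v$hairpin_ok)
    expect_equal(v$functional, e < -18)
  }
  # stem boundary at 18 pairs
  for (p in c(17L, 18L)) {
    s <- .stem_structure(p)
    v <- classify(s$seq, s$structure)
    expect_equal(v$stem_ok, p >= 18L)
    expect_true(v$energy_ok && v$mature_ok && v$hairpin_ok)
  }
  # mature-region loop boundary at > 5 nt per side
  for (sz in c(5L, 6L)) {
    pre <- make_precursor(22L, 4L, defects = list(
      list(type = "internal", at = 10L, size5 = sz, size3 = sz)))
    v <- classify(pre$seq, pre$structure, arms = pre$arms)
    expect_equal(v$mature_ok, sz <= 5L)
    expect_true(v$energy_ok && v$stem_ok && v$hairpin_ok)
    expect_equal(v$measured$largest_mature_defect, sz)
  }
})

test_that("a stable fold with a large mature-arm loop is still non-functional", {
  # marsupial-like situation: strongly negative energy but a 10-nt
  # internal loop inside the 3p arm
  pre <- make_precursor(22L, 4L, defects = list(
    list(type = "internal", at = 12L, size5 = 1L, size3 = 10L)))
  st <- rna_structure(pre$structure$dotbracket, energy = -39.40)
  v <- classify(pre$seq, st, arms = pre$arms)
  expect_true(v$energy_ok)
  expect_false(v$mature_ok)
  expect_false(v$functional)
})

test_that("mature_region_defects reports planted defects and nothing else", {
  cfg <- classifier_config()
  clean <- make_precursor(20L, 4L)
  expect_length(mature_region_defects(decompose(clean$structure$dotbracket),
                                      clean$arms, cfg), 0L)
  # bulge of 6 on the 5p arm crosses the threshold; bulge of 5 does not
  for (sz in c(5L, 6L)) {
    pre <- make_precursor(20L, 4L, defects = list(
      list(type = "bulge", at = 8L, size5 = sz, size3 = 0L)))
    d <- mature_region_defects(decompose(pre$structure$dotbracket), pre$arms, cfg)
    expect_length(d, as.integer(sz > 5L))
    if (length(d)) {
      expect_equal(d[[1]]$arm, "5p")
      expect_equal(d[[1]]$size, 6L)
    }
  }
  expect_error(
    mature_region_defects(decompose("......"), clean$arms, cfg),
    "simple hairpin")
})

test_that("defect detection matches the planted layout over random recipes", {
  set.seed(71)
  cfg <- classifier_config()
  for (r in 1:25) {
    at <- sample(4:16, 1)
    sz5 <- sample(0:8, 1); sz3 <- sample(0:8, 1)
    if (sz5 == 0L && sz3 == 0L) sz5 <- 1L
    type <- if (sz5 == 0L || sz3 == 0L) "bulge" else "internal"
    pre <- make_precursor(20L, 4L, defects = list(
      list(type = type, at = at, size5 = sz5, size3 = sz3)))
    d <- mature_region_defects(decompose(pre$structure$dotbracket),
                               pre$arms, cfg)
    # oracle: planted sides larger than the threshold that fall inside an
    # arm (arms are 22 nt each side of the loop; stem+defect < 29 per
    # side, so every defect lies inside an arm here)
    expected <- sum(c(sz5, sz3) > 5L)
    expect_length(d, expected)
  }
})

test_that("verdicts are deterministic and recover synthetic ground truth", {
  pre <- make_precursor(22L, 4L)
  m <- energy_model("unit_pair")
  f <- fold_mfe(pre$seq, m)
  v1 <- classify(pre$seq, f)
  v2 <- classify(pre$seq, f)
  expect_identical(v1, v2)
  expect_true(v1$functional)
  # targeted loop-opening mutations destroy the verdict in >= 90% of runs
  n_bad <- 0L
  for (s in 1:40) {
    deg <- degrade_precursor(pre$seq, 8L, seed = s, mode = "loop_opening")
    fd <- fold_mfe(deg, m)
    vd <- tryCatch(classify(deg, fd), error = function(e) NULL)
    if (is.null(vd) || !vd$functional) n_bad <- n_bad + 1L
  }
  expect_gte(n_bad, 36L)
})

test_that("arms are validated against the precursor", {
  s <- .stem_structure(20L)
  expect_error(classify(s$seq, s$structure,
                        arms = mature_arms(c(0, 22), c(30, 60))),
               "outside")
  expect_error(mature_arms(c(5, 3), c(10, 20)))
  expect_error(mature_arms(c(0, 12), c(10, 20)), "overlap")
})
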