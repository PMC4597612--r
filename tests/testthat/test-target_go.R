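# Seed matching, duplex scoring, cutoff ranking and GO enrichment.

.mir <- "UCCGAGCCUGGGUCUCCCUCUU"  # 22 nt

test_that("seed match types are classified from the site context", {
  core_rc <- revcomp_rna_str(substr(.mir, 2, 7))
  m8_rc <- revcomp_rna_str(substr(.mir, 8, 8))
  # 8mer: m8 match + A across from position 1
  utr8 <- paste0("GGGGG", m8_rc, core_rc, "A", "GGGGG")
  m <- find_seed_matches(.mir, utr8, "u")
  expect_equal(nrow(m), 1L)
  expect_equal(m$match_type, "8mer")
  # 7mer-m8: no A
  m7 <- find_seed_matches(.mir, paste0("GGGGG", m8_rc, core_rc, "G"), "u")
  expect_equal(m7$match_type, "7mer-m8")
  # 7mer-A1: A but no m8 match
  m7a <- find_seed_matches(.mir, paste0("GGGGG", "A", core_rc, "A"), "u")
  expect_equal(m7a$match_type, "7mer-A1")
  # no complementarity at all
  expect_equal(nrow(find_seed_matches(.mir, strrep("C", 50), "u")), 0L)
  expect_error(find_seed_matches("ACGUACG", "ACGU"), "at least 8")
})

test_that("site discovery equals a brute-force window scan on random UTRs", {
  set.seed(29)
  for (r in 1:10) {
    utr <- random_rna(2000)
    m <- find_seed_matches(.mir, utr, "u")
    expect_equal(sort(m$core_start), sort(brute_seed_sites(.mir, utr)))
    # every reported site really contains the seed reverse complement
    for (i in seq_len(nrow(m))) {
      expect_equal(substr(utr, m$core_start[i] + 1, m$core_start[i] + 6),
                   revcomp_rna_str(substr(.mir, 2, 7)))
    }
  }
})

test_that("duplex scores match their closed forms and per-site oracle", {
  unit <- energy_model("unit_pair")
  rc_full <- revcomp_rna_str(.mir)
  utr <- paste0(strrep("C", 20), rc_full, strrep("C", 10))
  m <- find_seed_matches(.mir, utr, "u")
  sc <- score_target(.mir, utr, m, unit)
  expect_equal(sc$score, -22)
  # seed-only site: exactly positions 2-8 pair; every other position faces
  # a base chosen to be non-complementary (A/C cannot pair G/U wobble in)
  nonpair <- c(A = "C", C = "A", G = "A", U = "C")
  mc <- strsplit(.mir, "")[[1]]
  left14 <- paste(nonpair[rev(mc[9:22])], collapse = "")
  utr2 <- paste0(strrep("C", 5), left14,
                 revcomp_rna_str(substr(.mir, 8, 8)),
                 revcomp_rna_str(substr(.mir, 2, 7)),
                 nonpair[mc[1]], strrep("C", 5))
  m2 <- find_seed_matches(.mir, utr2, "u")
  expect_equal(nrow(m2), 1L)
  sc2 <- score_target(.mir, utr2, m2, unit)
  expect_equal(sc2$score, -7)
  expect_error(score_target(.mir, utr2, m2[0, ], unit), "no seed-match")
  # min over sites equals scoring each site independently
  set.seed(43)
  for (r in 1:5) {
    utr3 <- paste0(random_rna(300), revcomp_rna_str(substr(.mir, 2, 8)),
                   random_rna(300), revcomp_rna_str(substr(.mir, 2, 8)),
                   random_rna(100))
    m3 <- find_seed_matches(.mir, utr3, "u")
    per_site <- vapply(seq_len(nrow(m3)), function(i) {
      score_target(.mir, utr3, m3[i, ], unit)$score
    }, numeric(1))
    expect_equal(score_target(.mir, utr3, m3, unit)$score, min(per_site))
  }
})

test_that("a seed match bounds the unit-pair score", {
  set.seed(47)
  unit <- energy_model("unit_pair")
  for (r in 1:10) {
    utr <- paste0(random_rna(100), revcomp_rna_str(substr(.mir, 2, 7)),
                  random_rna(100))
    m <- find_seed_matches(.mir, utr, "u")
    expect_gte(nrow(m), 1L)
    expect_lte(score_target(.mir, utr, m, unit)$score, -6)
  }
})

test_that("cutoff retention is inclusive, sorted, and matches a direct filter", {
  rt <- rank_targets(data.frame(utr_id = c("a", "b", "c"),
                                score = c(-25, -20, -15)))
  expect_equal(rt$utr_id, c("a", "b"))
  expect_equal(rt$score, c(-25, -20))
  expect_equal(nrow(rank_targets(data.frame(utr_id = character(0),
                                            score = numeric(0)))), 0L)
  set.seed(59)
  sims <- data.frame(utr_id = sprintf("g%03d", 1:200),
                     score = round(runif(200, -40, 0), 2))
  rt2 <- rank_targets(sims, cutoff = -20)
  expect_equal(nrow(rt2), sum(sims$score <= -20))
  expect_false(is.unsorted(rt2$score))
})

test_that("hypergeometric enrichment is exact and BH-corrected", {
  ann <- data.frame(gene = c(paste0("t", 1:5), paste0("t", 11:55)),
                    term = "GO:toy")
  res <- go_enrichment(paste0("t", 1:10), paste0("t", 1:1000), ann)
  expect_equal(res$fold_enrichment, 10)
  expect_equal(res$p, hyper_tail_sum(5, 50, 1000, 10), tolerance = 1e-12)
  # targets == background: fold 1, p 1
  res2 <- go_enrichment(paste0("t", 1:100), paste0("t", 1:100),
                        data.frame(gene = paste0("t", 1:30), term = "GO:x"))
  expect_equal(res2$fold_enrichment, 1)
  expect_equal(res2$p, 1)
  # term annotating no target: fold 0, p 1 (upper tail)
  res3 <- go_enrichment(c("t1", "t2"), paste0("t", 1:50),
                        data.frame(gene = c("t40", "t41"), term = "GO:z"))
  expect_equal(res3$fold_enrichment, 0)
  expect_equal(res3$p, 1)
  expect_error(go_enrichment(character(0), "t1", ann), "empty target")
  expect_error(go_enrichment("zz", "t1", ann), "subset")
  expect_warning(
    go_enrichment("t1", c("t1", "t2"),
                  data.frame(gene = c("t1", "qq"), term = c("GO:a", "GO:b"))),
    "skipping")
})

test_that("enrichment is invariant to gene relabeling and q >= p", {
  set.seed(61)
  genes <- sprintf("g%03d", 1:200)
  ann <- data.frame(gene = sample(genes, 300, TRUE),
                    term = sample(paste0("GO:", 1:8), 300, TRUE))
  targets <- sample(genes, 25)
  res <- go_enrichment(targets, genes, ann)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_false(is.unsorted(res$p))
  # relabel every gene consistently
  relab <- stats::setNames(sprintf("x%03d", 1:200), genes)
  ann2 <- transform(ann, gene = unname(relab[gene]))
  res2 <- go_enrichment(unname(relab[targets]), unname(relab[genes]), ann2)
  expect_equal(res$p, res2$p)
  expect_equal(res$q, res2$q)
})
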