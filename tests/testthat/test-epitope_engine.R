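test_that("peptide enumeration yields all k-windows in order", {
  s15 <- strrep("ACDEF", 3)
  expect_equal(nrow(enumerate_peptides(s15, 15)), 1L)
  expect_equal(enumerate_peptides(s15, 15)$peptide, s15)
  expect_equal(nrow(enumerate_peptides(substr(s15, 1, 14), 15)), 0L)
  s20 <- strrep("ACDEF", 4)
  pep <- enumerate_peptides(s20, 15)
  expect_equal(nrow(pep), 6L)
  expect_equal(pep$start, 0:5)
  expect_equal(pep$peptide, substring(s20, 1:6, 15:20))
  expect_error(enumerate_peptides("ACDEFGHIKLMNPQRSTVWX", 15), "amino-acid")
})

test_that("self filter retains exactly the windows overlapping a variant residue", {
  set.seed(42)
  base <- paste(sample(c("A", "C", "D", "E", "F", "G"), 30, TRUE), collapse = "")
  # donor differs from the recipient at (0-based) position 17 only
  donor <- base
  substr(donor, 18, 18) <- if (substr(base, 18, 18) == "W") "Y" else "W"
  peps <- enumerate_peptides(donor, 15)
  kept <- filter_self_peptides(peps, recipient_sequences = base)
  # brute-force substring oracle
  oracle <- vapply(peps$peptide, function(p) !grepl(p, base, fixed = TRUE),
                   logical(1), USE.NAMES = FALSE)
  expect_identical(kept$peptide, peps$peptide[oracle])
  # and those are exactly the windows whose [start, start+15) covers 17
  expect_identical(kept$start, peps$start[peps$start <= 17 & peps$start + 15 > 17])

  expect_identical(filter_self_peptides(peps, character(0)), peps)
  expect_equal(nrow(filter_self_peptides(peps, donor)), 0L)
})

test_that("surrogate predictor is deterministic with correct rank and affinity", {
  pred <- small_predictor(background_n = 2000L)
  pep <- strrep("ACDEH", 3)
  b1 <- predict_binding(pred, pep, "DRB1*03")
  b2 <- predict_binding(pred, pep, "DRB1*03")
  expect_identical(b1, b2)
  # a fresh predictor object with the same seed reproduces bit-identically
  b3 <- predict_binding(small_predictor(background_n = 2000L), pep, "DRB1*03")
  expect_identical(b1, b3)

  # affinity is a strictly decreasing transform of the raw score and the
  # 1000 nM criterion is equivalent to raw_score > log(A/1000)/b
  expect_equal(b1$affinity_nM, pred$A * exp(-pred$b * b1$raw_score))
  expect_equal(b1$affinity_nM < 1000, b1$raw_score > log(pred$A / 1000) / pred$b)

  # percentile rank equals the brute-force position within the rescored
  # background (independent recomputation of PWM and background scores)
  bg_raw <- pircher:::pwm_score_matrix(pred$bg,
                                       pircher:::predictor_pwm(pred, "DRB1*03"))
  expect_equal(b1$percentile_rank, 100 * mean(bg_raw >= b1$raw_score))
  for (probe in c("AAAAAAAAAAAAAAA", "YYYYYYYYYYYYYYY", strrep("KLM", 5))) {
    b <- predict_binding(pred, probe, "DRB1*03")
    expect_equal(b$percentile_rank, 100 * mean(bg_raw >= b$raw_score))
  }

  expect_error(predict_binding(pred, pep, "A*01"), "unknown presenter")
})

test_that("score_pair satisfies identity, aggregation, and mode-limit properties", {
  ctl <- small_catalog()
  pred <- small_predictor()
  m3 <- predictor_mode("affinity_v3")
  m4 <- predictor_mode("rank_v4")

  same <- seeded_pair(ctl, 1)
  same <- transplant_pair(same$recipient, same$recipient)
  for (m in list(m3, m4)) {
    sc <- score_pair(same, ctl, m, pred)
    expect_true(all(sc$per_locus == 0L))
    expect_equal(sc$total, 0L)
  }

  for (seed in 1:10) {
    p <- seeded_pair(ctl, seed)
    expect_score_identities(score_pair(p, ctl, m3, pred))
    expect_score_identities(score_pair(p, ctl, m4, pred))
  }

  # two modes with pass-everything criteria give identical tables
  p <- seeded_pair(ctl, 3)
  all3 <- score_pair(p, ctl, predictor_mode("affinity_v3", threshold = 1e12), pred)
  all4 <- score_pair(p, ctl, predictor_mode("rank_v4", threshold = 100), pred)
  expect_identical(all3$per_locus, all4$per_locus)
  expect_identical(all3$total, all4$total)
})

test_that("scores are monotone in thresholds and in added mismatched alleles", {
  ctl <- small_catalog()
  pred <- small_predictor()
  for (seed in c(2, 5, 9)) {
    p <- seeded_pair(ctl, seed)
    prev3 <- NULL
    for (thr in c(200, 1000, 5000, 1e12)) {
      sc <- score_pair(p, ctl, predictor_mode("affinity_v3", thr), pred)
      if (!is.null(prev3)) {
        expect_true(all(sc$per_locus >= prev3$per_locus))
        expect_true(sc$total >= prev3$total)
      }
      prev3 <- sc
    }
    prev4 <- NULL
    for (thr in c(2, 10, 50, 100)) {
      sc <- score_pair(p, ctl, predictor_mode("rank_v4", thr), pred)
      if (!is.null(prev4)) {
        expect_true(all(sc$per_locus >= prev4$per_locus))
        expect_true(sc$total >= prev4$total)
      }
      prev4 <- sc
    }
  }

  # widening the donor genotype with an extra mismatched allele never
  # decreases any component
  m3 <- predictor_mode("affinity_v3")
  for (seed in c(4, 8)) {
    p <- seeded_pair(ctl, seed)
    locus <- "B"
    av <- ctl$entries$allele[ctl$entries$locus == locus]
    d <- p$donor
    d[[locus]] <- d[[locus]][1]
    base_pair <- transplant_pair(genotype(d), p$recipient)
    extra <- setdiff(av, c(d[[locus]], p$recipient[[locus]]))[1]
    d2 <- d
    d2[[locus]] <- c(d[[locus]], extra)
    wide_pair <- transplant_pair(genotype(d2), p$recipient)
    s0 <- score_pair(base_pair, ctl, m3, pred)
    s1 <- score_pair(wide_pair, ctl, m3, pred)
    expect_true(all(s1$per_locus >= s0$per_locus))
    expect_true(s1$total >= s0$total)
  }
})

test_that("score_cohort pairs both modes, skips failures, compresses under rank mode", {
  ctl <- small_catalog()
  pred <- small_predictor()
  same <- seeded_pair(ctl, 1)
  same <- transplant_pair(same$recipient, same$recipient)
  tab <- score_cohort(list(ID1 = same), ctl, predictor = pred)
  expect_equal(tab$total_v3, 0L)
  expect_equal(tab$total_v4, 0L)
  expect_equal(tab$class1_v3 + tab$class2_v3, 0L)

  # a failing patient is recorded and skipped, the pipeline continues
  bad <- transplant_pair(
    genotype(A = "A*01", DRB1 = "DRB1*01"),
    genotype(B = "B*01", DRB1 = "DRB1*01"))
  pairs <- list(OK = seeded_pair(ctl, 2), BAD = bad)
  expect_warning(tab2 <- score_cohort(pairs, ctl, predictor = pred), "skipped")
  expect_equal(tab2$patient_id, "OK")
  expect_named(attr(tab2, "skipped"), "BAD")

  # determinism: identical inputs give identical tables
  pairs3 <- setNames(lapply(1:10, function(s) seeded_pair(ctl, s)), paste0("P", 1:10))
  t1 <- score_cohort(pairs3, ctl, predictor = small_predictor())
  t2 <- score_cohort(pairs3, ctl, predictor = small_predictor())
  expect_identical(t1, t2)

  # under calibrated defaults the rank criterion passes fewer tuples:
  # paired totals shift downward (one-sided signed-rank)
  big <- make_toy_catalog(length = 120L, rate = 0.1, seed = 3L)
  pairs4 <- sample_genotypes(default_allele_freqs(big), 100L, seed = 21L)
  t4 <- score_cohort(pairs4, big, predictor = small_predictor())
  expect_lt(median(t4$total_v4), median(t4$total_v3))
  w <- wilcox.test(t4$total_v3, t4$total_v4, paired = TRUE,
                   alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.01)
})
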