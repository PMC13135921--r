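test_that("Wilcoxon comparisons: degenerate pairs, extreme separation, guards", {
  same <- compare_score_groups(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  sep <- compare_score_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(sep$statistic), 0)  # all 9 cross-pairs concordant
  expect_lt(sep$p_value, 0.1)

  expect_error(compare_score_groups(1, c(1, 2)), "insufficient")
  expect_error(compare_score_groups(c(1, 2), c(1, 2, 3), paired = TRUE),
               "aligned")
})

test_that("AUC equals the Mann-Whitney concordance probability", {
  expect_equal(suppressWarnings(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(roc_auc(c(2, 2, 2, 2), c(0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(c(1, 2, 3), c(1, 1, 1)), "undefined")

  # brute-force cross-pair oracle on tied integer scores
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:60, 1)
    sc <- sample(0:8, n, replace = TRUE)
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, auc_brute(sc, lb))
  }

  # Youden threshold: perfect separation recovers sens = spec = 1
  r <- suppressWarnings(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), predefined_cutoff = 2))
  expect_equal(r$youden_sensitivity, 1)
  expect_equal(r$youden_specificity, 1)
  expect_true(r$youden_threshold > 2 && r$youden_threshold < 3)
  expect_equal(r$cutoff_sensitivity, 1)   # both positives exceed 2
  expect_equal(r$cutoff_specificity, 1)   # both negatives at or below 2
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
})

test_that("tertile and binary stratification follow the boundary conventions", {
  st <- assign_tertiles(1:9)
  expect_equal(as.integer(table(st$group)), c(3L, 3L, 3L))
  expect_warning(flat <- assign_tertiles(rep(2, 10)), "degenerate")
  expect_equal(nlevels(droplevels(flat$group)), 1L)

  set.seed(1)
  big <- assign_tertiles(rnorm(1000))
  expect_lte(diff(range(table(big$group))), 1L)
  expect_equal(sum(table(big$group)), 1000L)  # groups partition the cohort

  bs <- binary_stratify(c(0, 15, 16), 15)
  expect_equal(as.character(bs$group), c("<=15", "<=15", ">15"))
  expect_warning(binary_stratify(c(5, 6), 10), "empty")
  labs <- levels(binary_stratify(c(10, 20), 14.8)$group)
  expect_identical(labs, c("<=14.8", ">14.8"))
})

test_that("threshold recalibration matches low-group proportions", {
  ref <- c(0, 5, 10, 15, 20, 25)
  expect_equal(recalibrate_threshold(ref, 15, ref)$cutoff, 15)

  scaled <- 0.8 * ref
  rc <- recalibrate_threshold(ref, 15, scaled)
  expect_equal(rc$cutoff, 12)
  expect_equal(rc$achieved_proportion, 4 / 6)
  expect_equal(rc$reference_proportion, 4 / 6)

  # a reference proportion exactly between two achievable ones -> lower cutoff
  tie <- recalibrate_threshold(c(1, 1, 1, 2), 1, c(10, 20))  # target 3/4
  expect_equal(tie$cutoff, 10)  # 1/2 and 1 equally distant; lower wins
})

test_that("Kaplan-Meier estimator and log-rank test behave canonically", {
  km <- km_logrank(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curves$surv, c(2 / 3, 1 / 3, 0))

  # no censoring: S(t) = 1 - ECDF(t) at every event time
  set.seed(8)
  t <- rexp(40, 0.3)
  km2 <- km_logrank(t, rep(1, 40))
  expect_equal(km2$curves$surv, 1 - ecdf(t)(km2$curves$time))

  # two identical groups: statistic 0, p = 1
  g <- rep(c("x", "y"), each = 3)
  km3 <- km_logrank(rep(c(1, 2, 3), 2), rep(1, 6), g)
  expect_equal(km3$chisq, 0)
  expect_equal(km3$p_value, 1)

  expect_error(km_logrank(c(1, 2), c(1, 1), factor(c("a", "a"), levels = c("a", "b"))),
               "zero subjects")

  # invariances: group-label permutation and common monotone time rescale
  set.seed(9)
  tt <- rexp(60, 0.2) + 0.01
  ee <- rbinom(60, 1, 0.7)
  gg <- factor(rep(c("a", "b"), 30))
  p0 <- km_logrank(tt, ee, gg)$p_value
  swap <- factor(ifelse(gg == "a", "b", "a"))
  expect_equal(km_logrank(tt, ee, swap)$p_value, p0)
  expect_equal(km_logrank(sqrt(tt), ee, gg)$p_value, p0)
})

test_that("Cox fits recover known hazard structure", {
  # two-group exponential data with true rate ratio 2
  set.seed(31)
  n <- 2000L
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * 2^x)
  cens <- pmin(t, 8)
  ev <- as.integer(t <= 8)
  f <- cox_fit(cens, ev, x, encoding = "per_sd")
  # per-SD scaling: log HR per SD = log(2) * sd(x); undo the scaling
  expect_lt(abs(f$log_hr / sd(x) - log(2)), 0.12)
  expect_equal(f$ties, "efron")

  # perfectly concordant risk ordering, no ties or censoring: C-index 1
  tt <- 10:1
  # monotone partial likelihood (perfect separation) legitimately hits the
  # iteration cap; the concordance itself is exact
  f2 <- suppressWarnings(cox_fit(tt, rep(1, 10), 1:10, encoding = "per_sd"))
  expect_equal(f2$cindex, 1.0)

  expect_error(cox_fit(1:5, rep(0, 5), 1:5), "zero events")
  expect_error(cox_fit(1:5, c(1, 0, 1, 0, 1), rep(2, 5)), "constant")

  # tertile encoding contrasts medium/high against low
  set.seed(32)
  sc <- runif(300, 0, 100)
  t3 <- rexp(300, 0.05 * exp(0.01 * sc))
  f3 <- cox_fit(pmin(t3, 10), as.integer(t3 <= 10), sc, encoding = "tertile")
  expect_named(f3$hr, c("medium", "high"))
  expect_length(f3$thresholds, 2L)
  expect_gt(f3$hr[["high"]], 1)
})

test_that("one-mismatch subgroup selects top and bottom quartiles", {
  cohort <- data.frame(nmm_DQB1 = c(rep(1L, 8), 0L, 2L),
                       DQB1_v4 = c(1:8, 50, 60))
  st <- one_mismatch_subset(cohort, "DQB1", "v4")
  expect_equal(cohort$DQB1_v4[st$index[st$group == "bottom"]], c(1, 2))
  expect_equal(cohort$DQB1_v4[st$index[st$group == "top"]], c(7, 8))

  matched <- data.frame(nmm_DQB1 = rep(0L, 20), DQB1_v4 = 0L)
  expect_error(one_mismatch_subset(matched, "DQB1", "v4"), "insufficient")
})

test_that("locus-specific event views censor events against other loci", {
  cohort <- data.frame(
    time_years = c(2, 3, 4),
    event = c(1L, 1L, 0L),
    target_locus = c("DQB1", "C", NA),
    stringsAsFactors = FALSE)
  vC <- locus_event_view(cohort, "C")
  expect_equal(vC$events, c(0L, 1L, 0L))
  expect_equal(vC$times, c(2, 3, 4))  # DQ event censored at its event time
  vB <- locus_event_view(cohort, "B")
  expect_true(all(vB$events == 0L))
  # per-locus event counts partition the total event count
  per_locus <- vapply(c("A", "B", "C", "DRB1", "DQB1"),
                      function(l) sum(locus_event_view(cohort, l)$events), 1L)
  expect_equal(sum(per_locus), sum(cohort$event))
  expect_error(locus_event_view(cohort, "DPB1"), "unknown locus")
})

test_that("a cohort duplicated as both centers evaluates like its combination", {
  study <- get_default_study()
  d <- study$basel
  bundle <- run_full_evaluation(list(c1 = d, c2 = d))
  cb <- bundle$cohorts
  expect_equal(cb$combined$n, 2L * cb$c1$n)
  expect_equal(cb$combined$prevalence, cb$c1$prevalence)
  expect_equal(cb$combined$median_followup_years, cb$c1$median_followup_years)
  for (lab in c("v3", "v4")) {
    expect_equal(cb$combined[[lab]]$auc$total$auc, cb$c1[[lab]]$auc$total$auc)
    expect_equal(cb$combined[[lab]]$cox_tertile$cindex,
                 cb$c1[[lab]]$cox_tertile$cindex, tolerance = 0.01)
    expect_equal(unlist(cb$combined[[lab]]$tertiles$thresholds),
                 unlist(cb$c1[[lab]]$tertiles$thresholds), tolerance = 0.01)
  }
})
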