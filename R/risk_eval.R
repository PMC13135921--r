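## risk_eval: the evaluation battery applied to scored cohorts.
##
## Conventions fixed across the package: binary cutoffs are inclusive on
## the low side (groups "<= c" and "> c"); tertile boundary ties go to the
## lower group; Cox models use Efron tie handling (recorded in output);
## AUC confidence intervals use DeLong by default with a seeded stratified
## bootstrap as an option; p-values are reported raw, with no multiplicity
## adjustment.

#' Wilcoxon comparison of two score vectors
#'
#' Rank-sum for independent groups, signed-rank for paired (aligned)
#' scores. A paired comparison with no nonzero differences is reported as
#' p = 1 with a degenerate-input flag rather than an error.
#'
#' @param scores_a,scores_b numeric vectors (aligned and equal-length when
#'   `paired`).
#' @param paired logical.
#' @return List of class `score_test`: `statistic`, `p_value`, `method`,
#'   `degenerate`, `n`.
#' @export
compare_score_groups <- function(scores_a, scores_b, paired = FALSE) {
  if (paired && length(scores_a) != length(scores_b)) {
    stop("paired comparison requires aligned, equal-length vectors", call. = FALSE)
  }
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("insufficient data: need at least 2 observations per group", call. = FALSE)
  }
  method <- if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum"
  if (paired && all(scores_a == scores_b)) {
    return(structure(list(statistic = 0, p_value = 1, method = method,
                          degenerate = TRUE,
                          n = length(scores_a)),
                     class = "score_test"))
  }
  wt <- suppressWarnings(wilcox.test(scores_a, scores_b, paired = paired,
                                     exact = FALSE, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = method, degenerate = FALSE,
                 n = length(scores_a) + if (paired) 0L else length(scores_b)),
            class = "score_test")
}

#' ROC analysis of a score against a binary label
#'
#' AUC is the Mann-Whitney concordance probability (ties counted 1/2).
#' The Youden-optimal threshold maximizes sensitivity + specificity - 1,
#' with ties broken toward higher specificity. If `predefined_cutoff` is
#' given, its sensitivity/specificity are reported with positives called
#' at score > cutoff (cutoff inclusive on the low/negative side).
#'
#' @param scores numeric; higher = predicted higher risk.
#' @param labels 0/1 (both classes must be present).
#' @param ci_method `"delong"` (default) or `"bootstrap"` (stratified,
#'   `boot_n` resamples, seeded).
#' @param predefined_cutoff optional scalar cutoff to evaluate.
#' @param boot_n bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap CI.
#' @return List of class `roc_result`: `auc`, `ci` (2-vector), `ci_method`,
#'   `points` (threshold/sensitivity/specificity), `youden_threshold`,
#'   `youden_sensitivity`, `youden_specificity`, and, when requested,
#'   `cutoff`, `cutoff_sensitivity`, `cutoff_specificity`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    predefined_cutoff = NULL, boot_n = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("undefined AUC: both classes must be present", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- if (ci_method == "delong") {
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]
  } else {
    with_seed(seed, as.numeric(pROC::ci.auc(r, method = "bootstrap",
                                            boot.n = boot_n,
                                            boot.stratified = TRUE,
                                            progress = "none"))[c(1, 3)])
  }
  pts <- data.frame(threshold = r$thresholds,
                    sensitivity = r$sensitivities,
                    specificity = r$specificities)
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j == max(j))
  best <- best[order(pts$specificity[best], decreasing = TRUE)][1]
  out <- list(auc = auc, ci = ci, ci_method = ci_method, points = pts,
              youden_threshold = pts$threshold[best],
              youden_sensitivity = pts$sensitivity[best],
              youden_specificity = pts$specificity[best],
              n = length(scores), n_positive = sum(labels == 1L))
  if (!is.null(predefined_cutoff)) {
    out$cutoff <- predefined_cutoff
    out$cutoff_sensitivity <- mean(scores[labels == 1L] > predefined_cutoff)
    out$cutoff_specificity <- mean(scores[labels == 0L] <= predefined_cutoff)
  }
  structure(out, class = "roc_result")
}

#' @noRd
new_stratified_cohort <- function(group, thresholds, scheme, index = NULL) {
  structure(list(group = group, thresholds = thresholds, scheme = scheme,
                 index = index, sizes = table(group)),
            class = "stratified_cohort")
}

#' Tertile stratification of a score vector
#'
#' Cut points at the empirical 1/3 and 2/3 quantiles; boundary ties go to
#' the lower group (low <= q1 < medium <= q2 < high).
#'
#' @param scores numeric, length >= 3.
#' @return `stratified_cohort` with `group` (factor low/medium/high) and
#'   `thresholds = c(q1, q2)`.
#' @export
assign_tertiles <- function(scores) {
  stopifnot(length(scores) >= 3L)
  q <- unname(quantile(scores, c(1 / 3, 2 / 3), type = 7))
  if (length(unique(scores)) < 3L) {
    warning("degenerate stratification: fewer than 3 distinct score values",
            call. = FALSE)
  }
  group <- factor(ifelse(scores <= q[1], "low",
                         ifelse(scores <= q[2], "medium", "high")),
                  levels = c("low", "medium", "high"))
  new_stratified_cohort(group, q, "tertile")
}

#' Binary stratification at a cutoff
#'
#' Groups are `<= cutoff` and `> cutoff` (cutoff inclusive on the low
#' side). An empty group is flagged with a warning.
#'
#' @param scores numeric.
#' @param cutoff scalar threshold.
#' @return `stratified_cohort` with `group` levels `"<=c"` then `">c"`.
#' @export
binary_stratify <- function(scores, cutoff) {
  labs <- c(paste0("<=", cutoff), paste0(">", cutoff))
  group <- factor(ifelse(scores <= cutoff, labs[1], labs[2]), levels = labs)
  if (any(table(group) == 0L)) {
    warning("binary stratification at ", cutoff, " yields an empty group",
            call. = FALSE)
  }
  new_stratified_cohort(group, cutoff, "binary")
}

#' Recalibrate a threshold onto a new score distribution
#'
#' Finds the cutoff on the new scores whose low-group proportion best
#' matches the reference low-group proportion
#' `P(reference <= reference_cutoff)`; candidates are the observed new
#' scores (plus one value below the minimum, so a proportion of 0 is
#' achievable); proportion ties are broken toward the smaller cutoff.
#'
#' @param reference_scores numeric reference distribution.
#' @param reference_cutoff scalar cutoff on the reference scale.
#' @param new_scores numeric new-model scores.
#' @return List of class `recalibration`: `cutoff`,
#'   `achieved_proportion`, `reference_proportion`.
#' @export
recalibrate_threshold <- function(reference_scores, reference_cutoff, new_scores) {
  stopifnot(length(reference_scores) >= 1L, length(new_scores) >= 1L)
  pr <- mean(reference_scores <= reference_cutoff)
  cand <- c(min(new_scores) - 1, sort(unique(new_scores)))
  props <- vapply(cand, function(c) mean(new_scores <= c), 1.0)
  d <- abs(props - pr)
  i <- which(d == min(d))[1]  # candidates ascending => first = smallest cutoff
  structure(list(cutoff = cand[i], achieved_proportion = props[i],
                 reference_proportion = pr),
            class = "recalibration")
}

#' Kaplan-Meier curves and (optionally) the log-rank test
#'
#' Product-limit estimator per group; unstratified two-sided log-rank
#' chi-square with `groups - 1` degrees of freedom when at least two
#' groups are supplied.
#'
#' @param times positive follow-up/event times.
#' @param events 0/1 event indicators.
#' @param groups optional factor; a declared level with zero subjects is a
#'   stratification error.
#' @return List of class `survival_result`: `curves` (per-group data frame
#'   with `time`, `n_risk`, `n_event`, `surv`), and when tested `chisq`,
#'   `df`, `p_value`; plus `group_sizes`.
#' @export
km_logrank <- function(times, events, groups = NULL) {
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  if (is.null(groups)) groups <- factor(rep("all", length(times)))
  groups <- as.factor(groups)
  if (any(table(groups) == 0L)) {
    stop("stratification error: group with zero subjects", call. = FALSE)
  }
  df <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = df)
  sm <- summary(fit, censored = FALSE)
  strata <- if (is.null(sm$strata)) rep(levels(groups)[1], length(sm$time)) else {
    sub("^groups=", "", as.character(sm$strata))
  }
  curves <- data.frame(group = strata, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv,
                       stringsAsFactors = FALSE)
  out <- list(curves = curves, group_sizes = as.list(table(groups)))
  if (nlevels(groups) >= 2L) {
    lr <- survival::survdiff(survival::Surv(times, events) ~ groups, data = df)
    out$chisq <- lr$chisq
    out$df <- length(lr$n) - 1L
    out$p_value <- pchisq(lr$chisq, out$df, lower.tail = FALSE)
  }
  structure(out, class = "survival_result")
}

#' Cox proportional hazards fit with HR, CI and Harrell's C-index
#'
#' Partial-likelihood fit with Efron tie handling. For the continuous
#' encoding the covariate is standardized, so the hazard ratio is per SD;
#' for the tertile encoding the medium and high groups are contrasted
#' against low.
#'
#' @param times positive times.
#' @param events 0/1 event indicators (at least one event).
#' @param covariate numeric score (must vary).
#' @param encoding `"per_sd"` or `"tertile"`.
#' @return List of class `cox_result`: `hr`, `ci` (matrix with columns
#'   lower/upper), `p_values`, `cindex`, `ties = "efron"`, `encoding`,
#'   `n`, `n_events`, and `thresholds` for the tertile encoding.
#' @export
cox_fit <- function(times, events, covariate,
                    encoding = c("per_sd", "tertile")) {
  encoding <- match.arg(encoding)
  if (sum(events) < 1L) stop("cannot fit: zero events", call. = FALSE)
  if (length(unique(covariate)) < 2L) {
    stop("no information: covariate is constant", call. = FALSE)
  }
  thresholds <- NULL
  if (encoding == "per_sd") {
    x <- (covariate - mean(covariate)) / sd(covariate)
    df <- data.frame(times = times, events = events, x = x)
    fit <- survival::coxph(survival::Surv(times, events) ~ x, data = df,
                           ties = "efron")
  } else {
    st <- assign_tertiles(covariate)
    thresholds <- st$thresholds
    df <- data.frame(times = times, events = events, g = st$group)
    fit <- survival::coxph(survival::Surv(times, events) ~ g, data = df,
                           ties = "efron")
  }
  s <- summary(fit)
  ci <- s$conf.int[, c("lower .95", "upper .95"), drop = FALSE]
  hr <- s$conf.int[, "exp(coef)"]
  nm <- sub("^g", "", rownames(s$coefficients))
  if (encoding == "per_sd") nm <- "per_sd"
  structure(list(hr = setNames(as.numeric(hr), nm),
                 ci = matrix(as.numeric(ci), ncol = 2,
                             dimnames = list(nm, c("lower", "upper"))),
                 p_values = setNames(as.numeric(s$coefficients[, "Pr(>|z|)"]), nm),
                 cindex = as.numeric(s$concordance["C"]),
                 log_hr = setNames(as.numeric(s$coefficients[, "coef"]), nm),
                 se = setNames(as.numeric(s$coefficients[, "se(coef)"]), nm),
                 ties = "efron", encoding = encoding,
                 thresholds = thresholds,
                 n = length(times), n_events = sum(events)),
            class = "cox_result")
}

#' One-mismatch subgroup, stratified into top vs bottom score quartiles
#'
#' Restricts a cohort to patients with exactly one mismatched donor allele
#' at the locus, then contrasts the bottom (score <= Q1) and top
#' (score > Q3) quartiles of the locus score within that subset; the
#' middle half is excluded from the comparison.
#'
#' @param cohort cohort data frame with `nmm_<locus>` and
#'   `<locus>_<mode_label>` columns.
#' @param locus one of A, B, C, DRB1, DQB1.
#' @param mode_label score column suffix (e.g. `"v3"`, `"v4"`).
#' @return `stratified_cohort` whose `index` holds the cohort row numbers
#'   of the bottom/top quartile patients and `group` their labels.
#' @export
one_mismatch_subset <- function(cohort, locus, mode_label = "v4") {
  nmm_col <- paste0("nmm_", locus)
  score_col <- paste0(locus, "_", mode_label)
  stopifnot(nmm_col %in% names(cohort), score_col %in% names(cohort))
  idx <- which(cohort[[nmm_col]] == 1L)
  if (length(idx) < 8L) {
    stop("insufficient one-mismatch subset at ", locus, ": ",
         length(idx), " patients", call. = FALSE)
  }
  sc <- cohort[[score_col]][idx]
  q <- unname(quantile(sc, c(0.25, 0.75), type = 7))
  keep <- sc <= q[1] | sc > q[2]
  group <- factor(ifelse(sc[keep] <= q[1], "bottom", "top"),
                  levels = c("bottom", "top"))
  new_stratified_cohort(group, q, "one-mismatch-quartiles", index = idx[keep])
}

#' Locus-specific event view of a cohort
#'
#' Returns times/events where only dnDSA against the requested locus count
#' as events; patients with dnDSA against another locus are censored at
#' their event time (a documented choice; competing-risk estimators are
#' out of scope).
#'
#' @param cohort cohort data frame with `time_years`, `event`,
#'   `target_locus`.
#' @param locus one of A, B, C, DRB1, DQB1.
#' @return List with `times` and `events`.
#' @export
locus_event_view <- function(cohort, locus) {
  if (!locus %in% LOCI) stop("unknown locus: ", locus, call. = FALSE)
  ev <- as.integer(cohort$event == 1L &
                     !is.na(cohort$target_locus) &
                     cohort$target_locus == locus)
  list(times = cohort$time_years, events = ev)
}
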