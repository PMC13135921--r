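## Orchestration of the full evaluation battery over one or more cohorts.

#' @noRd
try_stage <- function(bundle_env, expr) {
  tryCatch(expr, error = function(e) {
    bundle_env$partial <- TRUE
    list(error = conditionMessage(e))
  })
}

#' @noRd
roc_brief <- function(r) {
  out <- list(auc = r$auc, ci_lower = r$ci[1], ci_upper = r$ci[2],
              ci_method = r$ci_method,
              youden_threshold = r$youden_threshold,
              youden_sensitivity = r$youden_sensitivity,
              youden_specificity = r$youden_specificity,
              n = r$n, n_positive = r$n_positive)
  if (!is.null(r$cutoff)) {
    out <- c(out, list(cutoff = r$cutoff,
                       cutoff_sensitivity = r$cutoff_sensitivity,
                       cutoff_specificity = r$cutoff_specificity))
  }
  out
}

#' @noRd
km_brief <- function(k) {
  out <- list(group_sizes = k$group_sizes)
  if (!is.null(k$p_value)) {
    out <- c(out, list(chisq = k$chisq, df = k$df, p_value = k$p_value))
  }
  out
}

#' @noRd
cox_brief <- function(cf) {
  list(encoding = cf$encoding, ties = cf$ties,
       hr = as.list(cf$hr),
       ci_lower = as.list(setNames(cf$ci[, "lower"], rownames(cf$ci))),
       ci_upper = as.list(setNames(cf$ci[, "upper"], rownames(cf$ci))),
       p_values = as.list(cf$p_values),
       cindex = cf$cindex,
       thresholds = if (is.null(cf$thresholds)) NULL else as.numeric(cf$thresholds),
       n = cf$n, n_events = cf$n_events)
}

#' Run the full risk-stratification evaluation
#'
#' For each cohort (and their pooled combination): paired old-vs-new score
#' comparisons (total and per locus); dnDSA-positive vs -negative rank-sum
#' comparisons and per-locus ROC/AUC under both modes; tertile
#' stratification of the total score with Kaplan-Meier/log-rank; the
#' locus-specific binary-threshold analysis at HLA-C (fixed reference
#' cutoff for the old model, recalibrated cutoff for the new); the
#' one-HLA-DQ-mismatch top-vs-bottom-quartile analysis; and Cox models of
#' the total score (tertile contrasts against low, plus per-SD), with
#' hazard ratios, 95% CIs and Harrell's C-index. All thresholds and group
#' sizes are recorded in the output. Any stage failure is recorded in
#' place and marks the bundle partial.
#'
#' @param cohorts named list of cohort data frames (as produced by
#'   [simulate_cohort()] / [simulate_study()]).
#' @param config list; supported fields `mode_labels` (default
#'   `c("v3", "v4")`), `hlac_reference_cutoff` (default 15),
#'   `one_mm_locus` (default `"DQB1"`), `ci_method` (default `"delong"`),
#'   `add_combined` (default TRUE when more than one cohort is given).
#' @return List of class `eval_bundle` with one entry per cohort plus
#'   `combined`, a `config` echo, and a `partial` flag.
#' @export
run_full_evaluation <- function(cohorts, config = list()) {
  labels <- config$mode_labels %||% c("v3", "v4")
  ref_cut <- config$hlac_reference_cutoff %||% 15
  one_mm_locus <- config$one_mm_locus %||% "DQB1"
  ci_method <- config$ci_method %||% "delong"
  add_combined <- config$add_combined %||% (length(cohorts) > 1L)
  if (add_combined && !"combined" %in% names(cohorts)) {
    combined <- do.call(rbind, lapply(cohorts, function(d) {
      rownames(d) <- NULL
      d
    }))
    rownames(combined) <- NULL
    cohorts <- c(cohorts, list(combined = combined))
  }
  env <- new.env()
  env$partial <- FALSE
  old <- labels[1]
  new <- labels[2]

  eval_one <- function(df) {
    ev <- df$event
    res <- list(
      n = nrow(df),
      n_events = sum(ev),
      prevalence = mean(ev),
      median_followup_years = median(df$followup_years),
      class2_event_share = if (sum(ev)) {
        mean(df$target_locus[ev == 1L] %in% CLASS2_LOCI)
      } else NA_real_
    )
    ## paired shift between scoring versions (total and per locus)
    res$score_shift <- try_stage(env, {
      cols <- c("total", LOCI)
      out <- lapply(cols, function(cl) {
        t <- compare_score_groups(df[[paste0(cl, "_", old)]],
                                  df[[paste0(cl, "_", new)]], paired = TRUE)
        list(p_value = t$p_value,
             median_old = median(df[[paste0(cl, "_", old)]]),
             median_new = median(df[[paste0(cl, "_", new)]]))
      })
      setNames(out, cols)
    })
    for (lab in labels) {
      m <- list()
      tot <- df[[paste0("total_", lab)]]
      m$group_comparison <- try_stage(env, {
        t <- compare_score_groups(tot[ev == 1L], tot[ev == 0L])
        list(p_value = t$p_value, statistic = t$statistic,
             median_positive = median(tot[ev == 1L]),
             median_negative = median(tot[ev == 0L]))
      })
      m$auc <- try_stage(env, {
        cols <- c("total", LOCI)
        setNames(lapply(cols, function(cl) {
          roc_brief(roc_auc(df[[paste0(cl, "_", lab)]], ev,
                            ci_method = ci_method))
        }), cols)
      })
      m$tertiles <- try_stage(env, {
        st <- assign_tertiles(tot)
        k <- km_logrank(df$time_years, ev, st$group)
        c(list(thresholds = as.numeric(st$thresholds)), km_brief(k))
      })
      m$hlac_binary <- try_stage(env, {
        cut <- if (lab == old) ref_cut else {
          recalibrate_threshold(df[[paste0("C_", old)]], ref_cut,
                                df[[paste0("C_", lab)]])$cutoff
        }
        st <- binary_stratify(df[[paste0("C_", lab)]], cut)
        v <- locus_event_view(df, "C")
        k <- km_logrank(v$times, v$events, st$group)
        c(list(cutoff = cut, recalibrated = lab != old), km_brief(k))
      })
      m$one_mismatch <- try_stage(env, {
        st <- one_mismatch_subset(df, one_mm_locus, mode_label = lab)
        k <- km_logrank(df$time_years[st$index], ev[st$index], st$group)
        c(list(locus = one_mm_locus, quartiles = as.numeric(st$thresholds)),
          km_brief(k))
      })
      m$cox_tertile <- try_stage(env, {
        cox_brief(cox_fit(df$time_years, ev, tot, encoding = "tertile"))
      })
      m$cox_per_sd <- try_stage(env, {
        cox_brief(cox_fit(df$time_years, ev, tot, encoding = "per_sd"))
      })
      res[[lab]] <- m
    }
    res
  }

  out <- lapply(cohorts, function(df) try_stage(env, eval_one(df)))
  structure(list(cohorts = out,
                 config = list(mode_labels = labels,
                               hlac_reference_cutoff = ref_cut,
                               one_mm_locus = one_mm_locus,
                               ci_method = ci_method),
                 partial = env$partial),
            class = "eval_bundle")
}

#' Write an evaluation bundle to JSON
#'
#' @param bundle an `eval_bundle` from [run_full_evaluation()].
#' @param path output path.
#' @param digits significant digits for numbers (default 10; fixed so
#'   repeated runs are byte-identical).
#' @export
write_eval_json <- function(bundle, path, digits = 10) {
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE,
                       digits = digits, null = "null", pretty = TRUE)
  invisible(path)
}

#' Flat CSV summary of an evaluation bundle
#'
#' One row per (cohort, mode, analysis, statistic) for the headline
#' statistics: AUC of the total score, log-rank p-values, tertile hazard
#' ratios, and C-index.
#'
#' @param bundle an `eval_bundle`.
#' @param path output CSV path.
#' @export
write_eval_summary_csv <- function(bundle, path) {
  rows <- list()
  add <- function(cohort, mode, analysis, statistic, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cohort = cohort, mode = mode, analysis = analysis,
      statistic = statistic, value = value, stringsAsFactors = FALSE)
  }
  for (cn in names(bundle$cohorts)) {
    cb <- bundle$cohorts[[cn]]
    if (!is.null(cb$error)) next
    add(cn, "", "cohort", "n", cb$n)
    add(cn, "", "cohort", "prevalence", cb$prevalence)
    add(cn, "", "cohort", "median_followup_years", cb$median_followup_years)
    for (lab in bundle$config$mode_labels) {
      m <- cb[[lab]]
      if (is.null(m)) next
      if (is.null(m$auc$error)) {
        add(cn, lab, "auc_total", "auc", m$auc$total$auc)
      }
      if (is.null(m$tertiles$error)) {
        add(cn, lab, "km_tertiles", "logrank_p", m$tertiles$p_value)
      }
      if (is.null(m$cox_tertile$error)) {
        add(cn, lab, "cox_tertile", "cindex", m$cox_tertile$cindex)
        add(cn, lab, "cox_tertile", "hr_high_vs_low", m$cox_tertile$hr$high)
      }
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
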