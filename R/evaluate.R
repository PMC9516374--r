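# Leave-one-out policy evaluation, paired t-test, agreement analysis.

#' Paired t-test of predicted versus observed values
#'
#' Computed from the closed formula: with differences `d = predicted -
#' observed`, `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of
#' freedom, two-sided p from the t distribution. Degenerate cases: all
#' differences exactly zero gives `t = 0, p = 1`; zero variance with a
#' nonzero mean gives an infinite t (p = 0) with a warning.
#'
#' @param predicted,observed equal-length numeric vectors (length >= 2).
#' @return list: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 2)
  d <- predicted - observed
  n <- length(d)
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    warning("zero-variance differences with nonzero mean: t is infinite")
    return(list(t = sign(m) * Inf, df = n - 1, p = 0, mean_diff = m))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1),
       mean_diff = m)
}

#' Agreement between recommended and observed actions
#'
#' Agreement at a stage is an exact match on both focus and intensity
#' (focus-only agreement is reported as a secondary measure). Patients are
#' stratified by agreement in both stages, exactly one, or neither, and the
#' observed cumulative composite outcome is summarized per stratum with a
#' normal-approximation 95% CI (`mean +/- 1.96 * sd / sqrt(n)`); empty strata
#' are reported with `NA` summaries.
#'
#' @param recommended,observed data.frames with per-patient columns
#'   `stage1_focus`, `stage1_intensity`, `stage2_focus`, `stage2_intensity`.
#' @param outcome numeric per-patient observed cumulative outcome.
#' @return list: per-stage agreement counts and percentages (exact and
#'   focus-only), `strata` data.frame (stratum, n, mean, ci_lo, ci_hi),
#'   per-patient stratum labels.
#' @export
agreement_analysis <- function(recommended, observed, outcome) {
  n <- nrow(recommended)
  stopifnot(nrow(observed) == n, length(outcome) == n)
  ag <- function(s) {
    as.character(recommended[[paste0("stage", s, "_focus")]]) ==
      as.character(observed[[paste0("stage", s, "_focus")]]) &
    as.character(recommended[[paste0("stage", s, "_intensity")]]) ==
      as.character(observed[[paste0("stage", s, "_intensity")]])
  }
  agf <- function(s) {
    as.character(recommended[[paste0("stage", s, "_focus")]]) ==
      as.character(observed[[paste0("stage", s, "_focus")]])
  }
  a1 <- ag(1); a2 <- ag(2)
  n_agree <- a1 + a2
  stratum <- factor(c("none", "one", "both")[n_agree + 1L],
                    levels = c("both", "one", "none"))
  strata <- do.call(rbind, lapply(levels(stratum), function(lv) {
    sel <- stratum == lv
    k <- sum(sel)
    if (k == 0)
      return(data.frame(stratum = lv, n = 0L, mean = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    m <- mean(outcome[sel])
    se <- if (k > 1) stats::sd(outcome[sel]) / sqrt(k) else NA_real_
    data.frame(stratum = lv, n = k, mean = m,
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
  }))
  list(stage1_agree_n = sum(a1), stage1_agree_pct = 100 * mean(a1),
       stage2_agree_n = sum(a2), stage2_agree_pct = 100 * mean(a2),
       stage1_focus_agree_pct = 100 * mean(agf(1)),
       stage2_focus_agree_pct = 100 * mean(agf(2)),
       strata = strata, stratum = stratum)
}

#' Leave-one-out cross-validated policy evaluation
#'
#' For each patient, the full pipeline (action shaping, reward scaling,
#' two-stage backward induction) is refit on the other `n - 1` patients and
#' the held-out patient's predicted policy value and recommended actions are
#' recorded. Under the default `full_cohort` scaling scope, the shaping
#' median and the reward scaling bounds are fit once on the whole cohort
#' (mirroring a single pre-analysis pass; this leaks modestly across folds);
#' under `train_fold` both are refit inside every training fold. The observed
#' comparator is the realized cumulative composite outcome of the coaching
#' actually delivered.
#'
#' @param cohort a cohort data.frame, n >= 3.
#' @param reward,shaping,regressor configuration objects.
#' @param candidates,stage2_target passed to [fit_policy()].
#' @param progress print a fold counter every 25 folds.
#' @return object of class `coach_eval`: `patients` (per-patient table),
#'   `mean_predicted`, `mean_observed`, `t_test`, `agreement`, `n_folds`,
#'   `failed_folds`, `config`.
#' @export
loocv_evaluate <- function(cohort, reward = reward_config(),
                           shaping = shaping_config(),
                           regressor = regressor_config(),
                           candidates = "observed",
                           stage2_target = "stage",
                           progress = FALSE) {
  n <- nrow(cohort)
  if (n < 3) stop("LOOCV needs a cohort of at least 3 patients")
  scope <- reward$scaling_scope

  full_shaped <- shape_actions(cohort, shaping)
  full_rewards <- stage_rewards(cohort, reward)
  full_bounds <- attr(full_rewards, "bounds")

  rows <- vector("list", n)
  failed <- character(0)
  for (i in seq_len(n)) {
    if (progress && i %% 25 == 0) qc_log("LOOCV fold ", i, "/", n)
    res <- tryCatch({
      train <- cohort[-i, , drop = FALSE]
      test <- cohort[i, , drop = FALSE]
      if (scope == "full_cohort") {
        pol <- fit_policy(train, reward, full_shaped$config, regressor,
                          candidates = candidates,
                          stage2_target = stage2_target, bounds = full_bounds)
        obs_rew <- full_rewards[i, ]
        obs_act <- full_shaped$actions[full_shaped$actions$patient_id ==
                                         cohort$patient_id[i], ]
      } else {
        pol <- fit_policy(train, reward, shaping, regressor,
                          candidates = candidates,
                          stage2_target = stage2_target)
        obs_rew <- stage_rewards(test, reward, bounds = pol$bounds)[1, ]
        obs_act <- shape_actions(test, pol$shaping)$actions
      }
      pred <- suppressWarnings(predict(pol, test))
      # secondary comparator: the Q-prediction at the observed stage-1 action
      ht <- assemble_histories(test, obs_act, manifest = pol$manifest)
      pred_at_obs <- q_predict(pol$q_stage1, ht$stage1,
                               obs_act[obs_act$stage == 1, ])
      data.frame(
        patient_id = cohort$patient_id[i],
        predicted_value = pred$policy_value,
        predicted_at_observed = pred_at_obs,
        observed_value = obs_rew$R,
        rec_stage1_focus = as.character(pred$stage1_focus),
        rec_stage1_intensity = as.character(pred$stage1_intensity),
        rec_stage2_focus = as.character(pred$stage2_focus),
        rec_stage2_intensity = as.character(pred$stage2_intensity),
        obs_stage1_focus = as.character(obs_act$focus[obs_act$stage == 1]),
        obs_stage1_intensity = as.character(obs_act$intensity[obs_act$stage == 1]),
        obs_stage2_focus = as.character(obs_act$focus[obs_act$stage == 2]),
        obs_stage2_intensity = as.character(obs_act$intensity[obs_act$stage == 2]),
        stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, cohort$patient_id[i])
      qc_log("LOOCV fold ", i, " failed: ", conditionMessage(res),
             level = "warn")
    } else rows[[i]] <- res
  }
  patients <- do.call(rbind, rows)
  if (length(failed))
    warning("aggregates computed over ", nrow(patients), " completed folds; ",
            length(failed), " fold(s) failed")

  rec <- data.frame(stage1_focus = patients$rec_stage1_focus,
                    stage1_intensity = patients$rec_stage1_intensity,
                    stage2_focus = patients$rec_stage2_focus,
                    stage2_intensity = patients$rec_stage2_intensity)
  obs <- data.frame(stage1_focus = patients$obs_stage1_focus,
                    stage1_intensity = patients$obs_stage1_intensity,
                    stage2_focus = patients$obs_stage2_focus,
                    stage2_intensity = patients$obs_stage2_intensity)
  agree <- agreement_analysis(rec, obs, patients$observed_value)
  patients$stratum <- as.character(agree$stratum)

  structure(list(
    patients = patients,
    n_folds = n, failed_folds = failed,
    mean_predicted = mean(patients$predicted_value),
    mean_observed = mean(patients$observed_value),
    t_test = paired_t(patients$predicted_value, patients$observed_value),
    agreement = agree[setdiff(names(agree), "stratum")],
    intensity_median = full_shaped$config$intensity_median,
    action_table = full_shaped$summary,
    config = list(reward = unclass(reward),
                  shaping = list(dominance_ratio = shaping$dominance_ratio,
                                 intensity_median = full_shaped$config$intensity_median),
                  regressor = unclass(regressor),
                  candidates = candidates, stage2_target = stage2_target,
                  scaling_scope = scope)),
    class = "coach_eval")
}

#' @export
print.coach_eval <- function(x, ...) {
  cat("LOOCV policy evaluation (", x$n_folds, " folds)\n", sep = "")
  cat(sprintf("  mean predicted policy value : %.3f\n", x$mean_predicted))
  cat(sprintf("  mean observed outcome       : %.3f\n", x$mean_observed))
  cat(sprintf("  paired t (df = %d)          : %.3f, p = %.3g\n",
              x$t_test$df, x$t_test$t, x$t_test$p))
  cat(sprintf("  stage-1 agreement           : %.1f%% (n = %d)\n",
              x$agreement$stage1_agree_pct, x$agreement$stage1_agree_n))
  cat(sprintf("  stage-2 agreement           : %.1f%% (n = %d)\n",
              x$agreement$stage2_agree_pct, x$agreement$stage2_agree_n))
  invisible(x)
}

#' @export
summary.coach_eval <- function(object, ...) {
  print(object)
  cat("\nAgreement-stratified observed cumulative outcome:\n")
  print(object$agreement$strata, row.names = FALSE)
  cat("\nObserved action table:\n")
  print(object$action_table, row.names = FALSE)
  invisible(object)
}

#' Serialize an evaluation report to JSON and a per-patient table
#'
#' @param eval_report a `coach_eval`.
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_eval_report <- function(eval_report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "evaluation.json")
  csv_path <- file.path(dir, "patients.csv")
  doc <- list(
    n_folds = eval_report$n_folds,
    failed_folds = eval_report$failed_folds,
    mean_predicted = eval_report$mean_predicted,
    mean_observed = eval_report$mean_observed,
    t = eval_report$t_test$t, df = eval_report$t_test$df,
    p = eval_report$t_test$p,
    agreement = eval_report$agreement,
    intensity_median = eval_report$intensity_median,
    config = eval_report$config)
  atomic_write(function(tmp)
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null"), json_path)
  atomic_write(function(tmp)
    utils::write.csv(eval_report$patients, tmp, row.names = FALSE), csv_path)
  invisible(c(json_path, csv_path))
}
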