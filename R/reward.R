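# Composite reward: per-stage relative changes, min-max scaling, weighting.

#' Reward configuration
#'
#' The composite per-stage outcome is
#' `w_hba1c * scaled HbA1c reduction + w_qol * scaled EQ-5D improvement`,
#' with both components min-max scaled to \[0, 1\] over the cohort before
#' weighting. Equal weights (0.5/0.5) reflect equal clinical importance of
#' glycemic control and quality of life and are the default.
#'
#' @param weight_hba1c,weight_qol nonnegative weights summing to 1.
#' @param scaling_scope where min-max bounds are fit during cross-validated
#'   evaluation: `"full_cohort"` (once, on all patients — mirrors a single
#'   pre-analysis scaling pass, leaks modestly) or `"train_fold"`
#'   (leakage-free, refit within each training fold).
#' @param constant_vector_value value assigned when a component is constant
#'   across the cohort (max = min); 0.5 keeps the composite defined and
#'   symmetric.
#' @param change enum: `"relative"` (default; change as a fraction of the
#'   stage baseline) or `"absolute"`.
#' @return object of class `reward_config`.
#' @export
reward_config <- function(weight_hba1c = 0.5, weight_qol = 0.5,
                          scaling_scope = c("full_cohort", "train_fold"),
                          constant_vector_value = 0.5,
                          change = c("relative", "absolute")) {
  if (weight_hba1c < 0 || weight_qol < 0 ||
      abs(weight_hba1c + weight_qol - 1) > 1e-8)
    stop("reward weights must be nonnegative and sum to 1")
  structure(list(weight_hba1c = weight_hba1c, weight_qol = weight_qol,
                 scaling_scope = match.arg(scaling_scope),
                 constant_vector_value = constant_vector_value,
                 change = match.arg(change)),
            class = "reward_config")
}

#' Relative change between a baseline and a follow-up measurement
#'
#' Signed fractional change oriented so that improvement is positive:
#' `(baseline - followup) / baseline` when a reduction is good (HbA1c),
#' `(followup - baseline) / baseline` when an increase is good (EQ-5D).
#' Worsening yields negative values.
#'
#' @param baseline positive numeric vector.
#' @param followup numeric vector.
#' @param direction `"reduction_good"` or `"increase_good"`.
#' @return numeric vector of signed fractions.
#' @export
relative_change <- function(baseline, followup,
                            direction = c("reduction_good", "increase_good")) {
  direction <- match.arg(direction)
  if (any(baseline <= 0, na.rm = TRUE))
    stop("relative change is undefined for baseline <= 0")
  if (direction == "reduction_good") (baseline - followup) / baseline
  else (followup - baseline) / baseline
}

#' Min-max scale a vector to \[0, 1\]
#'
#' With `bounds = NULL` the observed minimum and maximum are fit (and
#' returned), mapping the minimum to 0 and the maximum to 1. With fixed
#' `bounds`, values are scaled with those bounds and clipped to \[0, 1\] (for
#' held-out patients outside the fitted range). A constant vector maps to
#' `constant_value` everywhere, with a warning.
#'
#' @param values numeric vector (length >= 2 when fitting bounds).
#' @param bounds optional numeric `c(min, max)` from a previous fit.
#' @param constant_value value used when max = min (default 0.5).
#' @return list with `scaled` (vector in \[0, 1\]) and `bounds`.
#' @export
minmax_scale <- function(values, bounds = NULL, constant_value = 0.5) {
  fit <- is.null(bounds)
  if (fit) {
    if (length(values) < 2) stop("need >= 2 values to fit scaling bounds")
    bounds <- range(values, na.rm = TRUE)
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (hi <= lo) {
    if (fit) warning("constant vector: all values scaled to ", constant_value)
    scaled <- rep(constant_value, length(values))
    scaled[is.na(values)] <- NA_real_
  } else {
    scaled <- (values - lo) / (hi - lo)
    if (!fit) scaled <- clip01(scaled)
  }
  list(scaled = scaled, bounds = c(min = unname(lo), max = unname(hi)))
}

#' Weighted composite of the two scaled outcome components
#'
#' @param scaled_hba1c,scaled_qol scaled components in \[0, 1\].
#' @param config a [reward_config()].
#' @return composite outcome in \[0, 1\].
#' @export
composite_outcome <- function(scaled_hba1c, scaled_qol,
                              config = reward_config()) {
  config$weight_hba1c * scaled_hba1c + config$weight_qol * scaled_qol
}

#' Per-stage rewards and the cumulative composite outcome
#'
#' Stage 1 measures change from baseline to 6 months; stage 2 from 6 to 12
#' months. For each stage, the HbA1c reduction and EQ-5D improvement are
#' computed as (by default relative) changes, min-max scaled per component and
#' per stage, and combined with the configured weights into the composite
#' outcome `R1`/`R2` in \[0, 1\]; the cumulative reward is `R = R1 + R2` in
#' \[0, 2\]. When `bounds` are supplied (e.g. fit on a training fold), they
#' are applied with clipping; otherwise bounds are fit on this cohort and
#' returned in the `bounds` attribute.
#'
#' @param cohort cohort data.frame with the six outcome columns.
#' @param config a [reward_config()].
#' @param bounds optional scaling bounds from a previous fit (the `bounds`
#'   attribute of an earlier result).
#' @return data.frame of class `qc_rewards`: patient_id, raw/scaled components
#'   and composite per stage, cumulative `R`; attribute `bounds` = nested list
#'   `stage1`/`stage2` by component.
#' @export
stage_rewards <- function(cohort, config = reward_config(), bounds = NULL) {
  chg <- function(b, f, dir) {
    if (config$change == "relative") relative_change(b, f, dir)
    else if (dir == "reduction_good") b - f else f - b
  }
  raw <- list(
    stage1 = list(
      hba1c = chg(cohort$hba1c_t0, cohort$hba1c_t6, "reduction_good"),
      qol = chg(cohort$eq5d_t0, cohort$eq5d_t6, "increase_good")),
    stage2 = list(
      hba1c = chg(cohort$hba1c_t6, cohort$hba1c_t12, "reduction_good"),
      qol = chg(cohort$eq5d_t6, cohort$eq5d_t12, "increase_good")))
  fitted <- list(stage1 = list(), stage2 = list())
  scaled <- list(stage1 = list(), stage2 = list())
  for (s in c("stage1", "stage2")) for (comp in c("hba1c", "qol")) {
    sc <- minmax_scale(raw[[s]][[comp]], bounds = bounds[[s]][[comp]],
                       constant_value = config$constant_vector_value)
    scaled[[s]][[comp]] <- clip01(sc$scaled)
    fitted[[s]][[comp]] <- sc$bounds
  }
  R1 <- composite_outcome(scaled$stage1$hba1c, scaled$stage1$qol, config)
  R2 <- composite_outcome(scaled$stage2$hba1c, scaled$stage2$qol, config)
  out <- data.frame(
    patient_id = cohort$patient_id,
    raw_hba1c_1 = raw$stage1$hba1c, raw_qol_1 = raw$stage1$qol,
    scaled_hba1c_1 = scaled$stage1$hba1c, scaled_qol_1 = scaled$stage1$qol,
    R1 = R1,
    raw_hba1c_2 = raw$stage2$hba1c, raw_qol_2 = raw$stage2$qol,
    scaled_hba1c_2 = scaled$stage2$hba1c, scaled_qol_2 = scaled$stage2$qol,
    R2 = R2, R = R1 + R2, stringsAsFactors = FALSE)
  structure(out, bounds = fitted, class = c("qc_rewards", "data.frame"))
}

#' Export stage rewards in long (one row per patient-stage) form
#'
#' @param rewards a `qc_rewards` table from [stage_rewards()].
#' @return data.frame: patient_id, stage, raw/scaled components, composite,
#'   cumulative.
#' @export
rewards_long <- function(rewards) {
  long <- lapply(1:2, function(s) data.frame(
    patient_id = rewards$patient_id, stage = s,
    raw_hba1c = rewards[[paste0("raw_hba1c_", s)]],
    raw_qol = rewards[[paste0("raw_qol_", s)]],
    scaled_hba1c = rewards[[paste0("scaled_hba1c_", s)]],
    scaled_qol = rewards[[paste0("scaled_qol_", s)]],
    composite = rewards[[paste0("R", s)]],
    cumulative = rewards$R, stringsAsFactors = FALSE))
  out <- do.call(rbind, long)
  rownames(out) <- NULL
  out
}
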