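# Synthetic two-stage coaching cohort with analytic ground-truth Q-functions.
#
# Outcome model: per-stage HbA1c relative reduction and EQ-5D relative
# improvement are Gaussian with means linear in action indicators, a
# focus-by-covariate interaction (the "matched focus" bonus keyed to insulin
# use) and a standardized-age main effect:
#   hba1c_t6  = hba1c_t0 * (1 - drop1),  drop1 ~ N(mu_h(1, a1, z, age), sd_h)
#   hba1c_t12 = hba1c_t6 * (1 - drop2),  drop2 ~ N(mu_h(2, a2, z, age), sd_h)
# and analogously for EQ-5D gains. Modelling noise on the relative-change
# scale makes the raw reward components baseline-free, so expected stage
# rewards - and hence the true Q-functions and optimal policy - have exact
# closed forms.

#' Simulation parameters for the synthetic coaching cohort
#'
#' Defaults emulate the scale and marginals of a 177-patient two-stage
#' coaching trial: age ~ N(57.4, 11.3), 53.1% female, 39.5% insulin users,
#' baseline HbA1c ~ N(9.1, 1.7) truncated to \[5, 14\] percent, baseline
#' EQ-5D ~ Beta with mean 0.78 and sd 0.10. The behavior policy draws a
#' per-stage coaching intent (focus category + intensity arm); the total
#' recommendation count is Poisson (mean 5.5 low / 11 high, pooled median
#' about 8) and is allocated multinomially across the 9 types with 75% of
#' mass on the intended focus's member types. Psychological-support intent is
#' rare (2%), so that shaped action cells are realistically uneven. The
#' matched-focus interaction makes case-management coaching optimal for
#' insulin users and behavior-modification coaching optimal for the rest;
#' high intensity is uniformly beneficial.
#'
#' @param n cohort size.
#' @param seed integer seed; all generation is reproducible from it.
#' @param age_mean,age_sd,p_female,p_insulin covariate marginals.
#' @param hba1c0_mean,hba1c0_sd,hba1c0_range baseline HbA1c (truncated normal).
#' @param eq5d0_mean,eq5d0_sd baseline EQ-5D utility (Beta-distributed).
#' @param focus_intent_probs behavior-policy probabilities over intended focus
#'   (behavior, case, psych, general).
#' @param p_high probability of the high-intensity behavior arm.
#' @param total_mean_low,total_mean_high Poisson means of the per-stage total
#'   recommendation count by intensity arm.
#' @param focus_share multinomial mass on the intended focus's member types.
#' @param base_drop,base_gain length-2 stage intercepts of the HbA1c relative
#'   reduction and EQ-5D relative gain.
#' @param effect_high_hba1c,effect_high_eq5d high-intensity main effects.
#' @param effect_match_hba1c,effect_match_eq5d matched-focus interaction
#'   effects (focus = case management for insulin users, behavior
#'   modification otherwise). Setting both to 0 with the high effects gives
#'   the null scenario of no action effect.
#' @param age_coef_hba1c HbA1c-drop effect per SD of age.
#' @param sd_hba1c,sd_eq5d noise SDs of the relative changes.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n = 177, seed = 1L,
                       age_mean = 57.4, age_sd = 11.3,
                       p_female = 0.531, p_insulin = 0.395,
                       hba1c0_mean = 9.1, hba1c0_sd = 1.7,
                       hba1c0_range = c(5, 14),
                       eq5d0_mean = 0.78, eq5d0_sd = 0.10,
                       focus_intent_probs = c(behavior = 0.25, case = 0.35,
                                              psych = 0.02, general = 0.38),
                       p_high = 0.5,
                       total_mean_low = 5.5, total_mean_high = 11,
                       focus_share = 0.75,
                       base_drop = c(0.14, 0.02),
                       base_gain = c(0.02, 0.00),
                       effect_high_hba1c = 0.04, effect_high_eq5d = 0.03,
                       effect_match_hba1c = 0.06, effect_match_eq5d = 0.08,
                       age_coef_hba1c = 0.01,
                       sd_hba1c = 0.05, sd_eq5d = 0.08) {
  p <- as.list(environment())
  stopifnot(n >= 1, all(is.finite(unlist(p[!vapply(p, is.null, TRUE)]))),
            sd_hba1c >= 0, sd_eq5d >= 0,
            total_mean_low > 0, total_mean_high > 0,
            focus_share > 0, focus_share < 1,
            abs(sum(focus_intent_probs) - 1) < 1e-8,
            length(base_drop) == 2, length(base_gain) == 2)
  p$seed <- as.integer(seed)
  structure(p, class = "sim_params")
}

# matched-focus indicator: the focus that interacts positively with z
match_indicator <- function(focus, insulin) {
  f <- as.character(focus)
  as.numeric((insulin == 1 & f == "case_management_monitoring") |
             (insulin == 0 & f == "behavior_modification_education"))
}

# mean relative HbA1c drop / EQ-5D gain surfaces (vectorized)
mean_drop <- function(params, stage, focus, high, insulin, age_std) {
  params$base_drop[stage] + params$effect_high_hba1c * high +
    params$effect_match_hba1c * match_indicator(focus, insulin) +
    params$age_coef_hba1c * age_std
}

mean_gain <- function(params, stage, focus, high, insulin) {
  params$base_gain[stage] + params$effect_high_eq5d * high +
    params$effect_match_eq5d * match_indicator(focus, insulin)
}

#' Population min-max bounds of the raw relative changes
#'
#' Analytic large-range bounds used by the ground-truth Q-functions: the
#' extreme action-arm means plus/minus 4 noise SDs (age standardized to
#' \[-3, 3\] for the HbA1c component). Sample-free, so the oracle does not
#' depend on any realized cohort.
#'
#' @param params a [sim_params()].
#' @return nested list `stage1`/`stage2` by component (`hba1c`, `qol`), each
#'   `c(min, max)`.
#' @export
population_bounds <- function(params) {
  al <- action_levels()
  grid <- expand.grid(a = seq_len(nrow(al)), z = 0:1, age = c(-3, 3))
  out <- list()
  for (s in 1:2) {
    hi <- al$intensity[grid$a] == "high"
    mh <- mean_drop(params, s, al$focus[grid$a], as.numeric(hi), grid$z,
                    grid$age)
    mq <- mean_gain(params, s, al$focus[grid$a], as.numeric(hi), grid$z)
    out[[paste0("stage", s)]] <- list(
      hba1c = c(min = min(mh) - 4 * params$sd_hba1c,
                max = max(mh) + 4 * params$sd_hba1c),
      qol = c(min = min(mq) - 4 * params$sd_eq5d,
              max = max(mq) + 4 * params$sd_eq5d))
  }
  out
}

# scale a mean raw change with population bounds (no clipping: arm means are
# interior to the 4-sd bounds by construction)
pop_scale <- function(x, b) (x - b[1]) / (b[2] - b[1])

#' Ground-truth Q-function of the synthetic scenario
#'
#' Closed-form expected values under the outcome model, in composite-reward
#' units defined by [population_bounds()]. The stage-2 value is the expected
#' stage-2 composite for the given action; the stage-1 value is the expected
#' stage-1 composite plus the maximum stage-2 value (which does not depend on
#' the stage-1 action: the model has no cross-stage carry-over on the
#' relative-change scale).
#'
#' @param params a [sim_params()].
#' @param history data.frame with columns `insulin` and `age` (one row per
#'   patient).
#' @param stage 1 or 2.
#' @param action data.frame with `focus` and `intensity` (recycled to
#'   `nrow(history)` if one row).
#' @param reward a [reward_config()] supplying the component weights.
#' @return numeric vector of expected values.
#' @export
true_q <- function(params, history, stage, action, reward = reward_config()) {
  stopifnot(stage %in% c(1, 2))
  n <- nrow(history)
  if (nrow(action) == 1L) action <- action[rep(1, n), , drop = FALSE]
  b <- population_bounds(params)
  age_std <- (history$age - params$age_mean) / params$age_sd
  z <- history$insulin
  comp <- function(s, focus, high) {
    mh <- mean_drop(params, s, focus, high, z, age_std)
    mq <- mean_gain(params, s, focus, high, z)
    bb <- b[[paste0("stage", s)]]
    reward$weight_hba1c * pop_scale(mh, bb$hba1c) +
      reward$weight_qol * pop_scale(mq, bb$qol)
  }
  high <- as.numeric(as.character(action$intensity) == "high")
  if (stage == 2) return(comp(2, action$focus, high))
  v2 <- vapply(seq_len(nrow(action_levels())), function(k) {
    al <- action_levels()[k, ]
    comp(2, al$focus, as.numeric(al$intensity == "high"))
  }, numeric(n))
  if (n == 1L) v2 <- matrix(v2, nrow = 1)
  comp(1, action$focus, high) + apply(v2, 1, max)
}

#' Ground-truth optimal action
#'
#' Argmax of [true_q()] over the full 8-action space, ties broken by the
#' canonical action order (same rule as [greedy_action()]).
#'
#' @inheritParams true_q
#' @return data.frame of optimal actions (focus, intensity), one row per
#'   history row.
#' @export
true_optimal_action <- function(params, history, stage,
                                reward = reward_config()) {
  al <- action_levels()
  vals <- vapply(seq_len(nrow(al)), function(k)
    true_q(params, history, stage, al[k, , drop = FALSE], reward),
    numeric(nrow(history)))
  if (nrow(history) == 1L) vals <- matrix(vals, nrow = 1)
  best <- apply(vals, 1, which.max)
  out <- al[best, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# draw baseline covariates; returns data.frame
draw_baselines <- function(params, n) {
  age <- stats::rnorm(n, params$age_mean, params$age_sd)
  female <- stats::rbinom(n, 1, params$p_female)
  insulin <- stats::rbinom(n, 1, params$p_insulin)
  # truncated normal by inverse-cdf
  lo <- stats::pnorm(params$hba1c0_range[1], params$hba1c0_mean, params$hba1c0_sd)
  hi <- stats::pnorm(params$hba1c0_range[2], params$hba1c0_mean, params$hba1c0_sd)
  hba1c0 <- stats::qnorm(stats::runif(n, lo, hi),
                         params$hba1c0_mean, params$hba1c0_sd)
  m <- params$eq5d0_mean; v <- params$eq5d0_sd^2
  ab <- m * (1 - m) / v - 1
  eq5d0 <- stats::rbeta(n, m * ab, (1 - m) * ab)
  data.frame(age = age, female = female, insulin = insulin,
             hba1c_t0 = hba1c0, eq5d_t0 = eq5d0)
}

# behavior policy: draw 9-type counts for one stage; returns matrix n x 9
draw_counts <- function(params, n) {
  intents <- sample(names(params$focus_intent_probs), n, replace = TRUE,
                    prob = params$focus_intent_probs)
  high <- stats::rbinom(n, 1, params$p_high)
  totals <- stats::rpois(n, ifelse(high == 1, params$total_mean_high,
                                   params$total_mean_low))
  cmap <- default_category_map()
  members <- list(behavior = cmap[[1]], case = cmap[[2]], psych = cmap[[3]])
  counts <- matrix(0L, n, 9, dimnames = list(NULL, rec_types()))
  for (i in seq_len(n)) {
    p <- rep(1 / 9, 9)
    names(p) <- rec_types()
    if (intents[i] != "general") {
      mem <- members[[intents[i]]]
      p[] <- (1 - params$focus_share) / (9 - length(mem))
      p[mem] <- params$focus_share / length(mem)
    }
    if (totals[i] > 0)
      counts[i, ] <- as.integer(stats::rmultinom(1, totals[i], p))
  }
  counts
}

# realize one stage of outcomes given shaped actions; returns list of vectors
realize_stage <- function(params, stage, hba1c_prev, eq5d_prev, actions,
                          insulin, age_std) {
  n <- length(hba1c_prev)
  high <- as.numeric(as.character(actions$intensity) == "high")
  drop <- mean_drop(params, stage, actions$focus, high, insulin, age_std) +
    stats::rnorm(n, 0, params$sd_hba1c)
  gain <- mean_gain(params, stage, actions$focus, high, insulin) +
    stats::rnorm(n, 0, params$sd_eq5d)
  list(hba1c = hba1c_prev * (1 - drop), eq5d = eq5d_prev * (1 + gain))
}

#' Generate a synthetic two-stage coaching cohort with ground truth
#'
#' Draws baseline covariates, per-stage recommendation counts from the
#' behavior policy, shapes them into realized actions with the package's own
#' shaping rule (pooled-median intensity threshold, as the pipeline does),
#' and realizes 6- and 12-month outcomes from the outcome model given those
#' actions. Fully reproducible from `params$seed`.
#'
#' @param params a [sim_params()].
#' @return list with `cohort` (a `qc_cohort` in the standard trajectory
#'   schema) and `truth` (per-patient optimal actions per stage, optimal
#'   value, expected value of the realized behavior actions, and the fitted
#'   behavior shaping config).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n
  base <- draw_baselines(params, n)
  age_std <- (base$age - params$age_mean) / params$age_sd

  c1 <- draw_counts(params, n)
  c2 <- draw_counts(params, n)
  skeleton <- data.frame(patient_id = sprintf("P%04d", seq_len(n)), base,
                         check.names = FALSE)
  for (j in seq_len(9)) skeleton[[paste0("s1_", rec_types()[j])]] <- c1[, j]
  for (j in seq_len(9)) skeleton[[paste0("s2_", rec_types()[j])]] <- c2[, j]

  shaped <- shape_actions(skeleton, shaping_config())
  a1 <- shaped$actions[shaped$actions$stage == 1, ]
  a2 <- shaped$actions[shaped$actions$stage == 2, ]

  s1 <- realize_stage(params, 1, base$hba1c_t0, base$eq5d_t0, a1,
                      base$insulin, age_std)
  s2 <- realize_stage(params, 2, s1$hba1c, s1$eq5d, a2, base$insulin, age_std)
  skeleton$hba1c_t6 <- s1$hba1c
  skeleton$eq5d_t6 <- s1$eq5d
  skeleton$hba1c_t12 <- s2$hba1c
  skeleton$eq5d_t12 <- s2$eq5d

  cohort <- as_cohort(skeleton)
  hist_df <- data.frame(insulin = base$insulin, age = base$age)
  opt1 <- true_optimal_action(params, hist_df, 1)
  opt2 <- true_optimal_action(params, hist_df, 2)
  optimal_value <- true_q(params, hist_df, 1, opt1)
  # expected value of the realized behavior actions (stage composites at the
  # realized actions, population-scaled)
  b <- population_bounds(params)
  beh <- function(stage, acts) {
    high <- as.numeric(as.character(acts$intensity) == "high")
    mh <- mean_drop(params, stage, acts$focus, high, base$insulin, age_std)
    mq <- mean_gain(params, stage, acts$focus, high, base$insulin)
    bb <- b[[paste0("stage", stage)]]
    0.5 * pop_scale(mh, bb$hba1c) + 0.5 * pop_scale(mq, bb$qol)
  }
  behavior_value <- beh(1, a1) + beh(2, a2)

  truth <- list(
    optimal_stage1 = opt1, optimal_stage2 = opt2,
    optimal_value = optimal_value, behavior_value = behavior_value,
    realized_stage1 = a1[, c("focus", "intensity")],
    realized_stage2 = a2[, c("focus", "intensity")],
    shaping = shaped$config)
  list(cohort = cohort, truth = truth)
}

#' Monte-Carlo value of a policy under the synthetic scenario
#'
#' Simulates `n_mc` fresh patients, obtains each stage's action from
#' `policy`, realizes outcomes under the outcome model, and computes the
#' cumulative composite reward with fixed scaling bounds. This is the
#' independent, simulation-based check of a policy's value.
#'
#' @param policy one of: a fitted `coach_policy` (its recommendations and its
#'   stored scaling bounds are used unless `bounds` is given); the string
#'   `"oracle"` (ground-truth optimal actions), `"behavior"` (actions drawn
#'   from the behavior policy's counts) or `"random"` (uniform over the 8
#'   actions); or a function `(history_df, stage, prev)` returning an action
#'   data.frame.
#' @param params a [sim_params()].
#' @param n_mc number of simulated patients.
#' @param seed simulation seed.
#' @param bounds scaling bounds to compute rewards with (nested
#'   stage/component list); defaults to the policy's stored bounds for a
#'   `coach_policy` and to [population_bounds()] otherwise.
#' @param reward a [reward_config()].
#' @return list: `mean`, `se`, `values` (per-patient cumulative rewards).
#' @export
evaluate_policy_by_simulation <- function(policy, params, n_mc = 2000,
                                          seed = 1L, bounds = NULL,
                                          reward = reward_config()) {
  set.seed(seed)
  base <- draw_baselines(params, n_mc)
  age_std <- (base$age - params$age_mean) / params$age_sd
  hist_df <- data.frame(insulin = base$insulin, age = base$age)

  is_fitted <- inherits(policy, "coach_policy")
  if (is.null(bounds))
    bounds <- if (is_fitted) policy$bounds else population_bounds(params)

  counts_for <- function() draw_counts(params, n_mc)  # behavior draws
  behavior_shaping <- NULL
  get_actions <- function(stage, a1_prev, hba1c_prev, eq5d_prev) {
    if (is_fitted) {
      # assemble features the way the policy's manifest expects
      df <- data.frame(age = base$age, female = base$female,
                       insulin = base$insulin,
                       hba1c_t0 = base$hba1c_t0, eq5d_t0 = base$eq5d_t0)
      feats <- as.matrix(df[, policy$q_stage1$feature_names, drop = FALSE])
      if (stage == 1) return(recommend(policy, 1, feats)$action)
      enc <- encode_action(a1_prev$focus, a1_prev$intensity)
      f2 <- cbind(feats, a1_focus = enc[, "a_focus"], a1_high = enc[, "a_high"],
                  hba1c_t6 = hba1c_prev, eq5d_t6 = eq5d_prev)
      f2 <- f2[, policy$q_stage2$feature_names, drop = FALSE]
      return(recommend(policy, 2, f2)$action)
    }
    if (is.function(policy)) {
      df <- hist_df
      if (!is.null(hba1c_prev)) {
        df$hba1c_prev <- hba1c_prev
        df$eq5d_prev <- eq5d_prev
      }
      return(policy(df, stage, a1_prev))
    }
    switch(policy,
      oracle = true_optimal_action(params, hist_df, stage, reward),
      random = action_from_id(sample.int(8, n_mc, replace = TRUE)),
      behavior = {
        cnt <- counts_for()
        cats <- categorize_recommendations(cnt, shaping_config())
        tot <- rowSums(cnt)
        if (is.null(behavior_shaping)) {
          med <- stats::median(tot)
          behavior_shaping <<- shaping_config(intensity_median = med)
        }
        data.frame(focus = classify_focus(cats, behavior_shaping),
                   intensity = classify_intensity(tot, behavior_shaping))
      },
      stop("unknown policy spec: ", policy))
  }

  a1 <- get_actions(1, NULL, NULL, NULL)
  s1 <- realize_stage(params, 1, base$hba1c_t0, base$eq5d_t0, a1,
                      base$insulin, age_std)
  a2 <- get_actions(2, a1, s1$hba1c, s1$eq5d)
  s2 <- realize_stage(params, 2, s1$hba1c, s1$eq5d, a2, base$insulin, age_std)

  comp <- function(stage, b_raw, f_raw, eb, ef) {
    rh <- relative_change(b_raw, f_raw, "reduction_good")
    rq <- relative_change(eb, ef, "increase_good")
    bb <- bounds[[paste0("stage", stage)]]
    sh <- minmax_scale(rh, bounds = bb$hba1c)$scaled
    sq <- minmax_scale(rq, bounds = bb$qol)$scaled
    composite_outcome(sh, sq, reward)
  }
  values <- comp(1, base$hba1c_t0, s1$hba1c, base$eq5d_t0, s1$eq5d) +
    comp(2, s1$hba1c, s2$hba1c, s1$eq5d, s2$eq5d)
  list(mean = mean(values), se = stats::sd(values) / sqrt(n_mc),
       values = values)
}
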