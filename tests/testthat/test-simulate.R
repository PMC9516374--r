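test_that("generation is reproducible and validates its parameters", {
  p <- sim_params(n = 40, seed = 31)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_identical(a$truth$optimal_value, b$truth$optimal_value)
  expect_error(sim_params(sd_hba1c = -0.1))
  expect_error(sim_params(n = 0))
  # the generated table is a valid cohort in the standard schema
  rep <- validate_cohort(a$cohort)
  expect_equal(rep$negative_count + rep$missing_outcome +
                 rep$nonpositive_hba1c + rep$duplicate_id, 0)
})

test_that("zero noise reproduces the mean outcome surface exactly", {
  p <- sim_params(n = 30, seed = 32, sd_hba1c = 0, sd_eq5d = 0)
  sim <- generate_cohort(p)
  co <- sim$cohort
  a1 <- sim$truth$realized_stage1
  z <- co$insulin
  age_std <- (co$age - p$age_mean) / p$age_sd
  high <- as.numeric(as.character(a1$intensity) == "high")
  matched <- as.numeric((z == 1 & a1$focus == "case_management_monitoring") |
                        (z == 0 & a1$focus == "behavior_modification_education"))
  drop1 <- p$base_drop[1] + p$effect_high_hba1c * high +
    p$effect_match_hba1c * matched + p$age_coef_hba1c * age_std
  expect_equal(co$hba1c_t6, co$hba1c_t0 * (1 - drop1), tolerance = 1e-12)
})

test_that("the empirical outcome surface matches its configuration", {
  # large-sample Monte-Carlo check of the 6-month HbA1c mean under one arm
  p <- sim_params(n = 5000, seed = 33)
  sim <- generate_cohort(p)
  co <- sim$cohort
  a1 <- sim$truth$realized_stage1
  sel <- co$insulin == 1 & a1$focus == "case_management_monitoring" &
    a1$intensity == "high"
  expect_gt(sum(sel), 100)
  drops <- 1 - co$hba1c_t6[sel] / co$hba1c_t0[sel]
  age_std <- (co$age[sel] - p$age_mean) / p$age_sd
  expected <- p$base_drop[1] + p$effect_high_hba1c + p$effect_match_hba1c +
    p$age_coef_hba1c * age_std
  mc_se <- sd(drops - expected) / sqrt(sum(sel))
  expect_lt(abs(mean(drops - expected)), 3 * mc_se)
  # pooled median of recommendation totals sits at the emulated value
  med <- shape_actions(co)$config$intensity_median
  expect_equal(med, 8)
})

test_that("true_q reduces to main effects without interactions", {
  p <- sim_params(effect_match_hba1c = 0, effect_match_eq5d = 0)
  h <- data.frame(insulin = c(0, 1), age = c(50, 65))
  al <- action_levels()
  for (stage in 1:2) {
    v <- sapply(seq_len(8), function(k)
      true_q(p, h, stage, al[k, , drop = FALSE]))
    # with no interaction, action ordering is identical for both patients
    expect_equal(order(v[1, ]), order(v[2, ]))
    # high beats low within every focus, by a constant margin
    margins <- v[, seq(2, 8, 2)] - v[, seq(1, 8, 2)]
    expect_true(all(margins > 0))
    expect_equal(as.numeric(margins), rep(margins[1, 1], 8), tolerance = 1e-12)
  }
})

test_that("true_q matches a Monte-Carlo oracle on a discrete scenario", {
  p <- sim_params(seed = 34)
  h <- data.frame(insulin = 1, age = p$age_mean)
  act <- data.frame(focus = "case_management_monitoring", intensity = "high")
  v_analytic <- true_q(p, h, 2, act)
  # brute-force: draw stage-2 relative changes, scale with population bounds
  set.seed(340)
  nmc <- 1e5
  drops <- rnorm(nmc, p$base_drop[2] + p$effect_high_hba1c +
                   p$effect_match_hba1c, p$sd_hba1c)
  gains <- rnorm(nmc, p$base_gain[2] + p$effect_high_eq5d +
                   p$effect_match_eq5d, p$sd_eq5d)
  b <- population_bounds(p)$stage2
  vals <- 0.5 * (drops - b$hba1c[1]) / diff(b$hba1c) +
          0.5 * (gains - b$qol[1]) / diff(b$qol)
  expect_lt(abs(v_analytic - mean(vals)), 3 * sd(vals) / sqrt(nmc))
})

test_that("optimal actions track the interaction structure and tie-breaks", {
  p <- sim_params()
  h <- data.frame(insulin = c(1, 0), age = c(60, 60))
  for (stage in 1:2) {
    opt <- true_optimal_action(p, h, stage)
    expect_equal(as.character(opt$focus),
                 c("case_management_monitoring",
                   "behavior_modification_education"))
    expect_true(all(opt$intensity == "high"))
    # brute-force enumeration gives the same argmax
    al <- action_levels()
    vals <- sapply(seq_len(8), function(k)
      true_q(p, h, stage, al[k, , drop = FALSE]))
    expect_equal(as.character(opt$focus), as.character(al$focus[apply(vals, 1, which.max)]))
  }
  # flipping the interaction sign flips the favored focus for insulin users
  pf <- sim_params(effect_match_hba1c = -0.06, effect_match_eq5d = -0.08)
  optf <- true_optimal_action(pf, data.frame(insulin = 1, age = 60), 1)
  expect_false(as.character(optf$focus) == "case_management_monitoring")
  # with zero action effects every action ties -> canonical first action
  p0 <- sim_params(effect_match_hba1c = 0, effect_match_eq5d = 0,
                   effect_high_hba1c = 0, effect_high_eq5d = 0)
  opt0 <- true_optimal_action(p0, h, 1)
  expect_true(all(opt0$focus == "behavior_modification_education"))
  expect_true(all(opt0$intensity == "low"))
})

test_that("simulated policy values are ordered: random <= oracle, behavior <= optimal", {
  p <- sim_params(seed = 35)
  b <- population_bounds(p)
  orc <- evaluate_policy_by_simulation("oracle", p, n_mc = 1500, seed = 36,
                                       bounds = b)
  rnd <- evaluate_policy_by_simulation("random", p, n_mc = 1500, seed = 36,
                                       bounds = b)
  beh <- evaluate_policy_by_simulation("behavior", p, n_mc = 1500, seed = 36,
                                       bounds = b)
  se3 <- 3 * sqrt(orc$se^2 + rnd$se^2)
  expect_lte(rnd$mean, orc$mean + se3)
  expect_lte(beh$mean, orc$mean + 3 * sqrt(orc$se^2 + beh$se^2))
  expect_gt(orc$mean, rnd$mean)  # strict in this scenario
  # a custom function policy is accepted
  const_pol <- function(df, stage, prev)
    action_levels()[rep(2, nrow(df)), , drop = FALSE]
  cp <- evaluate_policy_by_simulation(const_pol, p, n_mc = 400, seed = 36,
                                      bounds = b)
  expect_true(is.finite(cp$mean))
  expect_lte(cp$mean, orc$mean + 3 * sqrt(orc$se^2 + cp$se^2))
})

test_that("per-patient ground-truth values dominate the behavior policy", {
  sim <- generate_cohort(sim_params(n = 60, seed = 37))
  expect_true(all(sim$truth$optimal_value >=
                    sim$truth$behavior_value - 1e-10))
})
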