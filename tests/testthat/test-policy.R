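test_that("tabular-mean Q-model predicts exact per-cell sample means", {
  # 2 binary covariates x 2 actions; oracle = tapply cell means
  set.seed(10)
  n <- 80
  x <- cbind(x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.5))
  acts <- data.frame(
    focus = sample(c("behavior_modification_education",
                     "case_management_monitoring"), n, replace = TRUE),
    intensity = "low", stringsAsFactors = FALSE)
  y <- rnorm(n)
  qm <- fit_stage_q(x, acts, y, regressor_config("tabular_mean"))
  pred <- qcoach:::q_predict(qm, x, acts)
  key <- paste(x[, 1], x[, 2], acts$focus)
  cell_means <- tapply(y, key, mean)
  expect_equal(pred, as.numeric(cell_means[key]))
})

test_that("constant targets give constant predictions for any action", {
  cohort <- toy_cohort(n = 15, seed = 11)
  shaped <- shape_actions(cohort)
  hs <- assemble_histories(cohort, shaped$actions)
  a1 <- shaped$actions[shaped$actions$stage == 1, ]
  for (method in c("tabular_mean", "gbm_hist", "linear")) {
    qm <- fit_stage_q(hs$stage1, a1, rep(0.7, 15),
                      regressor_config(method))
    vm <- qcoach:::q_value_matrix(qm, hs$stage1)
    expect_equal(as.numeric(vm), rep(0.7, length(vm)), tolerance = 1e-6)
  }
})

test_that("refitting with the same seed is bit-identical", {
  cohort <- toy_cohort(n = 30, seed = 12)
  shaped <- shape_actions(cohort)
  hs <- assemble_histories(cohort, shaped$actions)
  a1 <- shaped$actions[shaped$actions$stage == 1, ]
  y <- stage_rewards(cohort)$R
  for (method in c("gbm_hist", "random_forest")) {
    cfg <- regressor_config(method, seed = 99)
    p1 <- qcoach:::q_predict(fit_stage_q(hs$stage1, a1, y, cfg), hs$stage1, a1)
    p2 <- qcoach:::q_predict(fit_stage_q(hs$stage1, a1, y, cfg), hs$stage1, a1)
    expect_identical(p1, p2)
  }
})

test_that("greedy action breaks ties by canonical order and honors candidates", {
  cohort <- toy_cohort(n = 15, seed = 13)
  shaped <- shape_actions(cohort)
  hs <- assemble_histories(cohort, shaped$actions)
  a1 <- shaped$actions[shaped$actions$stage == 1, ]
  # constant model: every action has the same value -> canonical first wins
  qm <- fit_stage_q(hs$stage1, a1, rep(0.4, 15),
                    regressor_config("tabular_mean"),
                    candidates = action_levels())
  g <- greedy_action(qm, hs$stage1)
  expect_true(all(g$action$focus == "behavior_modification_education"))
  expect_true(all(g$action$intensity == "low"))
  expect_equal(g$value, rep(0.4, 15))
  # single candidate -> that candidate
  single <- action_levels()[5, , drop = FALSE]
  g1 <- greedy_action(qm, hs$stage1, candidates = single)
  expect_true(all(g1$action$focus == single$focus))
})

test_that("greedy equals brute-force argmax under a tabular model", {
  set.seed(14)
  n <- 120
  x <- cbind(x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.5))
  cand <- action_levels()[c(1, 2, 3, 4), ]
  ai <- sample(4, n, replace = TRUE)
  acts <- cand[ai, ]
  y <- rnorm(n, mean = x[, 1] * (ai == 2) - x[, 2] * (ai == 3))
  qm <- fit_stage_q(x, acts, y, regressor_config("tabular_mean"),
                    candidates = cand)
  g <- greedy_action(qm, x)
  # brute force: enumerate candidates, look up cell means by hand
  for (i in seq_len(n)) {
    vals <- vapply(seq_len(4), function(k) {
      key <- paste(x[i, 1], x[i, 2], cand$focus[k], cand$intensity[k])
      all_key <- paste(x[, 1], x[, 2], acts$focus, acts$intensity)
      if (key %in% all_key) mean(y[all_key == key]) else mean(y)
    }, numeric(1))
    k_star <- which.max(vals)
    expect_equal(as.character(g$action$focus[i]), as.character(cand$focus[k_star]))
    expect_equal(as.character(g$action$intensity[i]),
                 as.character(cand$intensity[k_star]))
    expect_equal(g$value[i], vals[k_star])
  }
})

test_that("backward induction with constant rewards yields value 2c everywhere", {
  cohort <- toy_cohort(n = 20, seed = 15)
  df <- as.data.frame(cohort)
  # no change on any measure -> every composite is the 0.5 midpoint
  df$hba1c_t6 <- df$hba1c_t0; df$hba1c_t12 <- df$hba1c_t0
  df$eq5d_t6 <- df$eq5d_t0; df$eq5d_t12 <- df$eq5d_t0
  flat <- as_cohort(df)
  pol <- suppressWarnings(
    fit_policy(flat, regressor = regressor_config("tabular_mean")))
  shaped <- shape_actions(flat, pol$shaping)
  hs <- assemble_histories(flat, shaped$actions, manifest = pol$manifest)
  v <- predicted_policy_value(pol, hs$stage1)
  expect_equal(v, rep(1, 20))  # R1 = R2 = 0.5 -> policy value 2 * 0.5
})

test_that("backward induction recommendations equal tabulated argmax at both stages", {
  cohort <- discrete_cohort(n = 64)
  pol <- suppressWarnings(
    fit_policy(cohort, regressor = regressor_config("tabular_mean")))
  shaped <- shape_actions(cohort, pol$shaping)
  rew <- suppressWarnings(stage_rewards(cohort))
  hs <- assemble_histories(cohort, shaped$actions, manifest = pol$manifest)
  a1 <- shaped$actions[shaped$actions$stage == 1, ]
  a2 <- shaped$actions[shaped$actions$stage == 2, ]

  # Independent brute force over exact feature cells (base R only).
  cell_key <- function(m) apply(m, 1, paste, collapse = "|")
  enc <- function(f, i) cbind(match(as.character(f), levels(action_levels()$focus)),
                              as.numeric(as.character(i) == "high"))
  cand2 <- unique(a2[order(qcoach:::action_id(a2$focus, a2$intensity)),
                     c("focus", "intensity")])
  cand1 <- unique(a1[order(qcoach:::action_id(a1$focus, a1$intensity)),
                     c("focus", "intensity")])
  # stage-2 cell means of R2 over (history2, a2)
  k2 <- cell_key(cbind(hs$stage2, enc(a2$focus, a2$intensity)))
  m2 <- tapply(rew$R2, k2, mean)
  q2hat <- function(i, k) {
    key <- paste(c(hs$stage2[i, ], enc(cand2$focus[k], cand2$intensity[k])),
                 collapse = "|")
    if (key %in% names(m2)) m2[[key]] else mean(rew$R2)
  }
  n <- nrow(cohort)
  best2 <- integer(n); max2 <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(seq_len(nrow(cand2)), function(k) q2hat(i, k), numeric(1))
    best2[i] <- which.max(vals); max2[i] <- max(vals)
  }
  pseudo <- rew$R1 + max2
  k1 <- cell_key(cbind(hs$stage1, enc(a1$focus, a1$intensity)))
  m1 <- tapply(pseudo, k1, mean)
  best1 <- integer(n)
  for (i in seq_len(n)) {
    vals <- vapply(seq_len(nrow(cand1)), function(k) {
      key <- paste(c(hs$stage1[i, ], enc(cand1$focus[k], cand1$intensity[k])),
                   collapse = "|")
      if (key %in% names(m1)) m1[[key]] else mean(pseudo)
    }, numeric(1))
    best1[i] <- which.max(vals)
  }

  pred <- suppressWarnings(predict(pol, cohort))
  expect_equal(as.character(pred$stage2_focus),
               as.character(cand2$focus[best2]))
  expect_equal(as.character(pred$stage2_intensity),
               as.character(cand2$intensity[best2]))
  expect_equal(as.character(pred$stage1_focus),
               as.character(cand1$focus[best1]))
  expect_equal(as.character(pred$stage1_intensity),
               as.character(cand1$intensity[best1]))
})

test_that("argmax dominance holds for every patient", {
  cohort <- toy_cohort(n = 60, seed = 16)
  pol <- fit_policy(cohort)
  shaped <- shape_actions(cohort, pol$shaping)
  hs <- assemble_histories(cohort, shaped$actions, manifest = pol$manifest)
  a1 <- shaped$actions[shaped$actions$stage == 1, ]
  a2 <- shaped$actions[shaped$actions$stage == 2, ]
  v_pol <- predicted_policy_value(pol, hs$stage1)
  v_obs1 <- qcoach:::q_predict(pol$q_stage1, hs$stage1, a1)
  expect_true(all(v_pol >= v_obs1 - 1e-10))
  v_max2 <- recommend(pol, 2, hs$stage2)$value
  v_obs2 <- qcoach:::q_predict(pol$q_stage2, hs$stage2, a2)
  expect_true(all(v_max2 >= v_obs2 - 1e-10))
})

test_that("fitting is deterministic end to end under a fixed seed", {
  cohort <- toy_cohort(n = 40, seed = 17)
  p1 <- fit_policy(cohort)
  p2 <- fit_policy(cohort)
  pr1 <- predict(p1, cohort)
  pr2 <- predict(p2, cohort)
  expect_identical(pr1, pr2)
})

test_that("a policy archive round-trips and refuses a mismatched schema", {
  cohort <- toy_cohort(n = 20, seed = 18)
  pol <- fit_policy(cohort)
  dir <- file.path(tempdir(), "polarch")
  save_policy(pol, dir)
  back <- load_policy(dir, schema = attr(cohort, "schema"))
  expect_identical(predict(back, cohort), predict(pol, cohort))
  other <- cohort_schema(covariates = data.frame(
    name = "unrelated", type = "numeric", timepoint = "baseline"))
  expect_error(load_policy(dir, schema = other), "schema")
  unlink(dir, recursive = TRUE)
})

test_that("with all weight on HbA1c and constant QoL, QoL transforms are irrelevant", {
  base <- as.data.frame(toy_cohort(n = 80, seed = 19))
  for (cl in c("eq5d_t0", "eq5d_t6", "eq5d_t12")) base[[cl]] <- 0.8
  cohort <- as_cohort(base)
  rw <- reward_config(weight_hba1c = 1, weight_qol = 0)
  warped <- base
  # arbitrary transformation of the (constant) EQ-5D inputs
  for (cl in c("eq5d_t0", "eq5d_t6", "eq5d_t12"))
    warped[[cl]] <- warped[[cl]]^2 / 2 + 0.1
  p1 <- suppressWarnings(fit_policy(cohort, reward = rw))
  p2 <- suppressWarnings(fit_policy(as_cohort(warped), reward = rw))
  a <- predict(p1, cohort)
  b <- predict(p2, as_cohort(warped))
  expect_equal(as.character(a$stage1_focus), as.character(b$stage1_focus))
  expect_equal(as.character(a$stage1_intensity),
               as.character(b$stage1_intensity))
})
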