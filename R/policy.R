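# Two-stage Q-learning by backward induction, and the fitted-policy object.

#' Fit a single-stage Q-model
#'
#' Regresses a value target on history features plus the encoded action
#' (focus as ordinal code, intensity as a binary indicator). Deterministic
#' given inputs and the config seed.
#'
#' @param features numeric history matrix (one row per patient).
#' @param actions data.frame with `focus` and `intensity` columns, one row per
#'   patient (the observed action at this stage).
#' @param targets numeric value target per patient.
#' @param config a [regressor_config()].
#' @param candidates data.frame of candidate actions for this stage (subset of
#'   [action_levels()]); defaults to the actions observed in `actions`, in
#'   canonical order.
#' @return object of class `q_model`.
#' @export
fit_stage_q <- function(features, actions, targets, config = regressor_config(),
                        candidates = NULL) {
  stopifnot(nrow(features) == nrow(actions), nrow(features) == length(targets))
  if (nrow(features) == 0L) stop("empty training set")
  if (is.null(candidates)) candidates <- observed_actions(actions)
  if (nrow(candidates) < 2L)
    warning("single observed action at this stage; the fitted Q-model is non-comparative")
  x <- cbind(features, encode_action(actions$focus, actions$intensity))
  reg <- fit_regressor(x, targets, config)
  structure(list(regressor = reg, feature_names = colnames(features),
                 candidates = candidates),
            class = "q_model")
}

# unique observed actions, canonical order
observed_actions <- function(actions) {
  ids <- sort(unique(action_id(actions$focus, actions$intensity)))
  action_from_id(ids)
}

q_predict <- function(model, features, action_df) {
  x <- cbind(features, encode_action(action_df$focus, action_df$intensity))
  predict_regressor(model$regressor, x)
}

# predicted value for every (row, candidate) pair: n x k matrix
q_value_matrix <- function(model, features, candidates = model$candidates) {
  n <- nrow(features); k <- nrow(candidates)
  big <- features[rep(seq_len(n), times = k), , drop = FALSE]
  acts <- candidates[rep(seq_len(k), each = n), , drop = FALSE]
  v <- q_predict(model, big, acts)
  matrix(v, nrow = n, ncol = k)
}

#' Greedy action under a fitted Q-model
#'
#' Returns, for each history, the candidate action with the largest predicted
#' value, together with that value. Ties are broken by the canonical action
#' order (first candidate wins), which is deterministic.
#'
#' @param model a `q_model` from [fit_stage_q()].
#' @param history numeric feature matrix (or single named vector) conforming
#'   to the model's feature manifest.
#' @param candidates candidate actions (default: the model's candidate set).
#' @return list with `action` (data.frame focus/intensity per row) and
#'   `value` (numeric vector of maxima).
#' @export
greedy_action <- function(model, history, candidates = model$candidates) {
  if (!is.matrix(history))
    history <- matrix(history, nrow = 1,
                      dimnames = list(NULL, names(history)))
  stopifnot(nrow(candidates) >= 1L)
  vm <- q_value_matrix(model, history, candidates)
  best <- apply(vm, 1, which.max)  # first max = canonical-order tie-break
  act <- candidates[best, , drop = FALSE]
  rownames(act) <- NULL
  list(action = act, value = vm[cbind(seq_len(nrow(vm)), best)])
}

#' Fit the two-stage coaching policy by backward induction
#'
#' The central fitting function. Given a cohort it (1) shapes the raw
#' recommendation counts into per-stage actions, (2) builds the composite
#' per-stage rewards, (3) fits the stage-2 Q-model on stage-2 histories and
#' observed stage-2 actions, (4) forms each patient's pseudo-outcome as the
#' stage-1 reward plus the maximized stage-2 Q-prediction, and (5) fits the
#' stage-1 Q-model against the pseudo-outcome. The returned object carries
#' every artifact needed to act on a new history: both Q-models, the scaling
#' bounds, the fitted shaping config and the encoding manifest.
#'
#' @param cohort a cohort data.frame (see [read_cohort()], [as_cohort()]).
#' @param reward a [reward_config()].
#' @param shaping a [shaping_config()]; an unset `intensity_median` is fit on
#'   this cohort.
#' @param regressor a [regressor_config()].
#' @param candidates `"observed"` (default) restricts each stage's candidate
#'   set to actions observed at least once in that stage; `"full"` uses the
#'   complete 8-action space (extrapolates beyond the data; a warning is
#'   issued).
#' @param stage2_target `"stage"` (default): the stage-2 Q-target is the
#'   stage-2 composite `R2` and the stage-1 pseudo-outcome is
#'   `R1 + max Q2`; `"cumulative"`: the stage-2 target is `R1 + R2` and the
#'   pseudo-outcome is `max Q2`.
#' @param bounds optional externally fitted scaling bounds (see
#'   [stage_rewards()]).
#' @return object of class `coach_policy`.
#' @export
fit_policy <- function(cohort, reward = reward_config(),
                       shaping = shaping_config(),
                       regressor = regressor_config(),
                       candidates = c("observed", "full"),
                       stage2_target = c("stage", "cumulative"),
                       bounds = NULL) {
  candidates <- match.arg(candidates)
  stage2_target <- match.arg(stage2_target)
  if (nrow(cohort) < 2L) stop("need at least 2 patients to fit a policy")

  shaped <- shape_actions(cohort, shaping)
  rew <- stage_rewards(cohort, reward, bounds = bounds)
  hs <- assemble_histories(cohort, shaped$actions)
  a1 <- shaped$actions[shaped$actions$stage == 1, ]
  a2 <- shaped$actions[shaped$actions$stage == 2, ]
  a1 <- a1[match(cohort$patient_id, a1$patient_id), ]
  a2 <- a2[match(cohort$patient_id, a2$patient_id), ]

  cand2 <- if (candidates == "full") action_levels() else observed_actions(a2)
  cand1 <- if (candidates == "full") action_levels() else observed_actions(a1)
  if (candidates == "full")
    warning("full 8-action candidate set: values for unobserved actions are extrapolations")

  target2 <- if (stage2_target == "stage") rew$R2 else rew$R
  q2 <- fit_stage_q(hs$stage2, a2, target2, regressor, candidates = cand2)
  max_q2 <- greedy_action(q2, hs$stage2)$value
  pseudo <- if (stage2_target == "stage") rew$R1 + max_q2 else max_q2
  q1 <- fit_stage_q(hs$stage1, a1, pseudo, regressor, candidates = cand1)

  structure(list(q_stage1 = q1, q_stage2 = q2,
                 bounds = attr(rew, "bounds"),
                 shaping = shaped$config, reward = reward,
                 regressor = regressor, manifest = hs$manifest,
                 schema = attr(cohort, "schema"),
                 candidates = list(stage1 = cand1, stage2 = cand2),
                 stage2_target = stage2_target,
                 training = list(n = nrow(cohort),
                                 action_table = shaped$summary,
                                 mean_R = mean(rew$R),
                                 pseudo_mean = mean(pseudo)),
                 call = match.call()),
            class = "coach_policy")
}

#' Recommend an action for a patient history
#'
#' Greedy action under the fitted stage Q-model, over that stage's candidate
#' set.
#'
#' @param policy a `coach_policy` from [fit_policy()].
#' @param stage 1 or 2.
#' @param history numeric feature matrix (rows = patients) conforming to that
#'   stage's feature manifest; for stage 2 this includes the encoded stage-1
#'   action and 6-month covariates (see [assemble_histories()]).
#' @return list with `action` and `value` as in [greedy_action()].
#' @export
recommend <- function(policy, stage, history) {
  stopifnot(inherits(policy, "coach_policy"), stage %in% c(1, 2))
  model <- if (stage == 1) policy$q_stage1 else policy$q_stage2
  greedy_action(model, history)
}

#' Predicted value of the learned policy for a baseline history
#'
#' The maximized stage-1 Q-prediction: the cumulative composite outcome the
#' model expects if both decisions follow the learned policy. By construction
#' it is at least the stage-1 Q-prediction at any particular action (argmax
#' dominance).
#'
#' @param policy a `coach_policy`.
#' @param stage1_history numeric baseline feature matrix.
#' @return numeric vector of predicted policy values.
#' @export
predicted_policy_value <- function(policy, stage1_history) {
  recommend(policy, 1, stage1_history)$value
}

#' Predict method: recommendations and values for a cohort
#'
#' Shapes the cohort's observed actions with the policy's stored shaping
#' config (for the stage-2 history), assembles histories with the stored
#' encoding manifest, and returns per-patient recommended actions and
#' predicted values for both stages plus the predicted policy value.
#'
#' @param object a `coach_policy`.
#' @param newdata a cohort data.frame.
#' @param ... unused.
#' @return data.frame: patient_id, recommended focus/intensity and predicted
#'   value per stage, `policy_value`.
#' @export
predict.coach_policy <- function(object, newdata, ...) {
  shaped <- shape_actions(newdata, object$shaping)
  hs <- assemble_histories(newdata, shaped$actions, manifest = object$manifest)
  r1 <- recommend(object, 1, hs$stage1)
  r2 <- recommend(object, 2, hs$stage2)
  data.frame(patient_id = newdata$patient_id,
             stage1_focus = r1$action$focus,
             stage1_intensity = r1$action$intensity,
             stage1_value = r1$value,
             stage2_focus = r2$action$focus,
             stage2_intensity = r2$action$intensity,
             stage2_value = r2$value,
             policy_value = r1$value,
             stringsAsFactors = FALSE)
}

#' @export
print.coach_policy <- function(x, ...) {
  cat("Two-stage Q-learning coaching policy\n")
  cat("  training patients:", x$training$n, "\n")
  cat("  regressor:", x$regressor$method, " seed:", x$regressor$seed, "\n")
  cat("  reward weights (hba1c/qol):", x$reward$weight_hba1c, "/",
      x$reward$weight_qol, "\n")
  cat("  intensity median:", x$shaping$intensity_median, "\n")
  cat("  candidate actions: stage1 =", nrow(x$candidates$stage1),
      ", stage2 =", nrow(x$candidates$stage2), "\n")
  invisible(x)
}

#' @export
summary.coach_policy <- function(object, ...) {
  print(object)
  cat("  mean observed cumulative reward:",
      round(object$training$mean_R, 4), "\n")
  cat("  mean stage-1 pseudo-outcome:",
      round(object$training$pseudo_mean, 4), "\n")
  cat("\nObserved action table:\n")
  print(object$training$action_table)
  invisible(object)
}

#' Persist a fitted policy to a versioned archive directory
#'
#' Writes the serialized policy plus a JSON manifest (package version, schema,
#' encoding manifest, configs). [load_policy()] refuses an archive whose
#' schema does not match the requested runtime schema.
#'
#' @param policy a `coach_policy`.
#' @param dir archive directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_policy <- function(policy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atomic_write(function(tmp) saveRDS(policy, tmp),
               file.path(dir, "policy.rds"))
  meta <- list(package = "qcoach",
               version = as.character(utils::packageVersion("qcoach")),
               schema = as.data.frame(policy$schema),
               manifest = policy$manifest,
               regressor = unclass(policy$regressor),
               reward = unclass(policy$reward),
               intensity_median = policy$shaping$intensity_median)
  atomic_write(function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE),
    file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname save_policy
#' @param schema optional runtime [cohort_schema()] the archive must match.
#' @export
load_policy <- function(dir, schema = NULL) {
  policy <- readRDS(file.path(dir, "policy.rds"))
  if (!inherits(policy, "coach_policy")) stop("archive does not hold a coach_policy")
  if (!is.null(schema)) {
    stored <- policy$schema
    if (!identical(sort(stored$name), sort(schema$name)))
      stop("policy archive schema does not match the runtime schema")
  }
  policy
}
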