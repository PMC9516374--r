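---
title: "Methods: two-stage Q-learning for adaptive health coaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage Q-learning for adaptive health coaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`qcoach` estimates an individualized two-stage coaching policy from
longitudinal diabetes health-coaching data. This vignette is the package's
account of the statistical method, its assumptions, the tunable parameters,
and the design decisions taken where more than one reasonable choice existed.

## The decision problem

Each patient is observed at baseline (t0), 6 months (t6) and 12 months
(t12). A coach selects an intervention in stage 1 (t0 → t6) and again in
stage 2 (t6 → t12). Writing `h1` for the baseline history, `a1` and `a2` for
the stage actions, and `R1`, `R2` for per-stage rewards, the target is the
policy `π = (π1, π2)` maximizing `E[R1 + R2]`. This is the standard two-stage
dynamic treatment regime, solved by Q-learning with backward induction:

1. Fit `Q2(h2, a2) = E[R2 | h2, a2]` on the observed stage-2 data, where
   `h2 = (h1, a1, 6-month covariates)`.
2. Form each patient's pseudo-outcome `R1 + max_a Q2(h2, a)` — the stage-1
   reward plus the value of acting optimally afterwards.
3. Fit `Q1(h1, a1)` against the pseudo-outcome.
4. The learned policy is the per-stage argmax; its *predicted policy value*
   for a baseline history is `max_a Q1(h1, a)`.

The key identification assumptions are those of any observational DTR
analysis: no unmeasured confounding given the recorded history, positivity
(every candidate action has support in every history region — which is why
candidate sets default to *observed* actions, see below), and consistency.
None of these can be verified from the data; the package makes the modelling
transparent, not the causality automatic.

An alternative formulation uses the cumulative outcome `R1 + R2` as the
stage-2 target and `max_a Q2` alone as the stage-1 pseudo-outcome; both
conventions appear in the DTR literature and are equivalent in the linear
case. The per-stage target is the default (`stage2_target = "stage"`), the
cumulative variant is config-selectable.

## The composite reward

Per stage, two components are computed as **relative changes** oriented so
that improvement is positive: HbA1c reduction `(baseline − followup) /
baseline` and EQ-5D improvement `(followup − baseline) / baseline`. Relative
(rather than absolute) change is the default because the canonical worked
example — HbA1c 7.0 → 6.8 described as a 2.86% reduction — is a relative
change; absolute change is available behind `reward_config(change =
"absolute")`. The stage-2 baseline is the 6-month value (t6 → t12), matching
the sequential framing in which each stage is rewarded for what happened on
its own watch.

Each component is min-max scaled to [0, 1] **per component and per stage**
over the cohort, then combined as a weighted average with default weights
0.5/0.5 (equal clinical importance of glycemic control and quality of life).
`R1, R2 ∈ [0, 1]`, `R = R1 + R2 ∈ [0, 2]`.

Numerical choices:

* **Stored bounds.** Scaling bounds are part of the fit and are reapplied,
  with clipping to [0, 1], to held-out patients who fall outside the fitted
  range.
* **Constant component.** If a component shows no variation (max = min) it
  is mapped to 0.5 everywhere, with a warning: symmetric, and keeps the
  composite defined.
* **Scaling scope.** `full_cohort` (default) fits bounds once on all
  patients, mirroring a single pre-analysis scaling pass; this leaks the
  held-out patient's changes into the scaling during LOOCV, but only through
  two cohort-level extrema. `train_fold` refits bounds within each fold for
  a strictly leakage-free evaluation. Both are first-class and recorded in
  reports.

## Action-space shaping

Raw data record per-stage counts of 9 recommendation types. These are
grouped (a fixed, clinically defined map) into 3 focus categories; a
category is the stage's **focus** iff its count is at least
`dominance_ratio = 2` times each other category's count — otherwise the
stage is *general coaching*. **Intensity** is high when the stage's total
count strictly exceeds the median of per-patient per-stage totals pooled
across both stages (one cohort-level median), low otherwise. This yields 8
actions: 4 foci × 2 intensities.

Deterministic edge rules (the shaping rule itself is silent on these):

* All-zero counts map to general + low.
* Ties at the median map to **low** (only strict "greater than the median"
  is high).
* A dominance winner must be strictly positive and unique; with ratio ≥ 2
  two simultaneous winners are impossible when both are positive, and the
  guard returns *general* if no unique winner exists.
* Tie-breaking for every argmax over actions uses the canonical order: foci
  in their listed order, low before high; the first action in canonical
  order is (behavior modification & education, low).

## Regressors

Any regression can stand behind a Q-function; the default is
**histogram-binned gradient-boosted trees** (`xgboost`, `tree_method =
"hist"`), chosen for many mixed-type covariates with interactions and native
missing-value handling. Defaults are 100 rounds, learning rate 0.1, depth 3,
a single thread and a fixed seed — library-typical values with no tuning
loop, since small cohorts cannot support honest tuning inside LOOCV.
Alternatives: `random_forest` (`ranger`), `linear` (`lm`), and
`tabular_mean`, which predicts exact per-cell sample means on discrete state
spaces and is the reference implementation against which the boosted path is
tested (on a discrete cohort, backward induction with `tabular_mean` must
equal brute-force argmax over cell means, exactly).

The action enters the regression as two features (ordinal focus code, binary
intensity) rather than 8 one-hot columns: tree models handle either, and
this keeps the stage-2 history encoding compact. Though tree "classification"
terminology is sometimes used loosely for this model family, the composite
outcome is continuous and the fit here is a regression.

**Candidate actions** default to those observed at least once in that
stage's training data: recommending a never-observed action would rest
purely on model extrapolation (and typically some cells — e.g.
psychological-support coaching — are rare or absent). The full 8-action
space is available via `candidates = "full"`, with a warning.

Categorical covariates are ordinal-encoded in lexicographic category order
recorded in a manifest — deterministic across runs, and harmless for tree
models, which are invariant to code ordering. A category unseen at fit time
maps to a designated code (0) with a logged warning. Patients missing any of
the six outcome values are excluded (the reward is undefined without them);
covariate missingness passes through as `NA` to the boosted trees, or is
median-imputed (imputation values stored at fit time) for the other methods.

## Evaluation

`loocv_evaluate()` refits the entire pipeline on each size-(n−1) training
set and records the held-out patient's predicted policy value and
recommended actions. The comparison baseline is the **realized** cumulative
composite outcome of the coaching actually delivered (not a model prediction
at the observed actions — the model-based variant is exported alongside).

* **Paired t-test** of predicted vs observed, `t = mean(d)/(sd(d)/√n)` on
  n − 1 degrees of freedom. Note the mechanism: by argmax dominance the
  predicted policy value is at least the Q-prediction at the observed
  action for every patient, so a positive gap is expected whenever the model
  sees heterogeneity; the test quantifies it but cannot separate true policy
  improvement from regression optimism. The simulator exists precisely to
  make that separation on known ground truth.
* **Agreement analysis**: exact (focus, intensity) match per stage
  (focus-only agreement exported as a secondary measure); patients stratified
  into both/one/none; per-stratum mean outcome with a normal-approximation
  95% CI (`mean ± 1.96·sd/√n`). The normal CI is the simplest defensible
  choice for a reporting summary; single-patient strata get no CI.
* One global regressor seed is used across all folds (per-fold seeds would
  add noise without adding validity).

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions of a 177-patient two-stage
coaching trial: age ~ N(57.4, 11.3); 53.1% female; 39.5% insulin-treated;
baseline HbA1c ~ N(9.1, 1.7) truncated to [5, 14]%; baseline EQ-5D ~ Beta
with mean 0.78, sd 0.10. The behavior policy draws a per-stage coaching
intent — focus category with probabilities (behavior 0.25, case 0.35, psych
0.02, general 0.38) and a high-intensity arm with probability 0.5 — then a
Poisson total (mean 5.5 low / 11 high, giving a pooled median of 8
recommendations) allocated multinomially with 75% of mass on the intended
focus's member types. Realized actions are obtained by running the package's
own shaping rule on the drawn counts, so generator and pipeline can never
disagree about labels; intent and realized action differ for a realistic
minority (dominance near-misses, totals at the median).

Outcomes are generated on the **relative-change scale**: the stage-s HbA1c
reduction is Gaussian with mean `base_drop[s] + 0.04·high + 0.06·match +
0.01·age_std` (sd 0.05), and the EQ-5D gain has mean `base_gain[s] +
0.03·high + 0.08·match` (sd 0.08), where `match` is the focus-by-covariate
interaction: case management is the matched focus for insulin users,
behavior modification for everyone else. Stage intercepts (HbA1c drop 0.14
then 0.02; EQ-5D gain 0.02 then 0.00) reproduce the 9.1 → 7.6 → 7.3 HbA1c
trajectory and a flat-ish EQ-5D at trial scale. Putting the noise on the
relative change (multiplicative on levels) is a deliberate deviation from
additive level noise: it makes the raw reward components baseline-free, so
the true Q-functions have exact closed forms (`true_q()`), the optimal
policy is analytic (matched focus + high intensity), and no numerical
integration or discretization is needed in the oracle. Ground-truth scaling
uses analytic *population* bounds (extreme arm means ± 4 sd) so the oracle
is sample-free.

What the generator does **not** emulate: the real trial's joint covariate
distribution (only marginal plausibility), missing data, EQ-5D ceiling
effects (simulated utilities may slightly exceed 1), human factors such as
adherence, and any cross-stage carry-over of the stage-1 action into
stage-2 outcomes. Consequently, passing the recovery tests shows the
estimator is correct under a faithful two-stage DTR data-generating process
with interaction-driven heterogeneity — it does not certify performance on
real coaching data, where confounding and model misspecification are live
concerns.

## Problem sizes and budgets used in the tests

Unit tests use cohorts of 3–80 patients. The policy-recovery study trains on
2,000 simulated patients, tests stage-wise agreement with the true optimal
policy on 500 fresh patients (criterion ≥ 90%), compares Monte-Carlo policy
values on 2,000 simulated patients (learned within 5% of oracle; null
scenario within 3 SE of the behavior policy), and the LOOCV demonstrations
use 50- and 177-patient cohorts — sizes chosen to keep the full suite
comfortably under a half hour on a single CPU while leaving Monte-Carlo
standard errors small relative to the tested margins.

## Known limitations

* Two stages only; no discounting, no off-policy importance-sampling or
  doubly-robust value estimators, no confidence intervals on Q-parameters.
* The predicted-vs-observed gap conflates policy improvement with regression
  optimism (see above); treat the paired t-test as descriptive of the model,
  not as causal evidence.
* `full_cohort` scaling and a cohort-level shaping median leak modestly
  across LOOCV folds; use `train_fold` scope when leakage matters more than
  comparability with the single-pass convention.
* The 9 → 3 category grouping and equal reward weights are fixed clinical
  choices, not estimated quantities.
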