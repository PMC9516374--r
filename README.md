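# qcoach

Estimating individualized two-stage **diabetes health-coaching policies**
with Q-learning.

## The problem

In a two-stage coaching program, a coach chooses an intervention for each
patient at two decision points (the initial visit and a 6-month follow-up),
and outcomes are observed at 6 and 12 months. The clinical question is a
dynamic treatment regime (DTR) problem: *which coaching action should a given
patient receive at each stage, based on their accumulated history, to
maximize a composite of glycemic control and quality of life?*

`qcoach` implements the full analysis pipeline for this question:

1. **Composite reward.** For each stage the HbA1c reduction and EQ-5D
   improvement are computed as relative changes, min-max scaled to [0, 1]
   over the cohort, and combined with equal weights:
   `R_s = 0.5 * scaled HbA1c reduction + 0.5 * scaled EQ-5D improvement`.
   The cumulative reward `R = R1 + R2` in [0, 2] is what the policy
   maximizes. Example: HbA1c 7.0 → 6.8 (a 2.86% reduction, scaled 0.835) and
   EQ-5D 0.457 → 0.533 (scaled 0.504) give `0.5·0.835 + 0.5·0.504 = 0.670`.
2. **Action-space shaping.** Nine recommendation types are grouped into three
   focus categories (behavior modification & education; case management &
   monitoring; psychological support). A stage's focus is the category with
   at least twice as many recommendations as each other category (otherwise
   *general coaching*), and its intensity is *high* when the total
   recommendation count exceeds the cohort median — yielding an 8-action
   space (4 foci × 2 intensities).
3. **Q-learning by backward induction.** The stage-2 Q-function
   `Q2(h2, a2) ≈ E[R2]` is fit by regression (histogram gradient boosting by
   default); each patient's pseudo-outcome `R1 + max_a Q2(h2, a)` then
   becomes the stage-1 target for `Q1(h1, a1)`. The learned policy is
   `π_s(h) = argmax_a Q_s(h, a)`.
4. **Evaluation.** Leave-one-out cross-validation (LOOCV) refits the whole
   pipeline n times; the held-out patient's predicted policy value is
   compared with their realized outcome by a paired t-test, and the policy's
   recommendations are compared with the coaches' observed actions
   (agreement analysis with agreement-stratified outcome means).
5. **Synthetic cohorts with ground truth.** A trajectory simulator emulates
   a 177-patient two-stage coaching trial with a known, covariate-dependent
   optimal policy and closed-form true Q-functions, so the whole pipeline is
   testable end to end without any external data.

## Worked example

```r
library(qcoach)

sim <- generate_cohort(sim_params(n = 177, seed = 7))  # synthetic trial
ev  <- loocv_evaluate(sim$cohort)                      # 177-fold LOOCV
summary(ev)
```

```
LOOCV policy evaluation (177 folds)
  mean predicted policy value : 1.185
  mean observed outcome       : 0.974
  paired t (df = 176)          : 12.656, p = 1.6e-26
  stage-1 agreement           : 15.3% (n = 27)
  stage-2 agreement           : 14.1% (n = 25)

Agreement-stratified observed cumulative outcome:
 stratum   n      mean    ci_lo     ci_hi
    both   5 1.2240884 1.015815 1.4323615
     one  42 1.1208011 1.063703 1.1778990
    none 130 0.9169329 0.883100 0.9507658
```

Reading this: the model's expected cumulative composite outcome under its
own recommendations (1.185) exceeds the realized outcome of the observed
coaching (0.974), a gap that is mechanically driven by argmax dominance and
is tested with a paired t-test on 176 degrees of freedom. The policy agrees
with the human coaches for a minority of patients, and patients whose
coaching happened to match the policy in both stages had the best observed
outcomes (1.224 vs 0.917 for patients matching in neither stage).

Fitting a deployable policy on the full cohort:

```r
pol <- fit_policy(sim$cohort)
print(pol)
#> Two-stage Q-learning coaching policy
#>   training patients: 177
#>   regressor: gbm_hist  seed: 1
#>   reward weights (hba1c/qol): 0.5 / 0.5
#>   intensity median: 8
predict(pol, sim$cohort)   # per-patient recommended actions + values
```

A thin command-line wrapper is installed at `inst/cli/qcoach.R`
(`simulate` / `fit` / `evaluate` subcommands over a YAML config).

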