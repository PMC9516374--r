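Package: qcoach
Title: Two-Stage Q-Learning for Adaptive Health-Coaching Policies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individualized two-stage coaching policies from
    longitudinal diabetes health-coaching trial data. Builds a composite
    reward from min-max-scaled HbA1c reduction and EQ-5D quality-of-life
    improvement, shapes raw coaching-recommendation counts into a compact
    focus-by-intensity action space, fits stage-wise Q-functions by backward
    induction with a pluggable regressor (histogram gradient boosting by
    default), and evaluates the learned policy with leave-one-out
    cross-validation, a paired t-test of predicted versus observed outcomes,
    and an agreement analysis against the observed coaching behavior. A
    synthetic trajectory simulator with analytic ground-truth Q-functions
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
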