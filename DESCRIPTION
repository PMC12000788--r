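Package: shiftadvice
Title: Simulation and Predictive Modelling of Physician Sleep Advice for
    Shift Workers
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying physician-curated sleep advice in rotating
    shift-worker cohorts tracked with wrist-worn devices and daily surveys.
    Provides a calibrated synthetic cohort generator (rotating
    day/afternoon/midnight shifts, shift-conditioned sleep, behaviour and
    well-being surveys, a rule-based advice policy over a 23-message
    catalog), minute-resolution sleep/work sequence construction with the
    sleep regularity index, daily feature engineering (sample entropy,
    segment-duration entropies, sleep-shift gaps), Ward clustering of
    behaviour profiles, per-message advice classifiers (bagged trees and
    two gradient-boosted tree families implemented natively) trained under
    user-dependent and user-independent splits with optional oversampling
    and SMOTE, AUPRC-based evaluation against random baselines with Welch
    tests, F1-optimal threshold ensembles, and permutation / Shapley
    feature-importance reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    FNN,
    jsonlite,
    Rcpp,
    Rtsne,
    stats,
    truncnorm,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
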