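Package: bkarisk
Title: Additive Risk Index and Outcome Analysis for Below-Knee Amputation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes a point-based risk index (range 0-12) for patients
    undergoing below-knee amputation from age band, six preoperative
    comorbid systemic diseases, postoperative mobilization category, and
    early postoperative hypoxia or metabolic disorder, together with the
    Katz activities-of-daily-living score. Provides from-scratch
    implementations of the nonparametric procedures used to validate such
    an index (exact and asymptotic Mann-Whitney U tests with tie and
    continuity corrections, empirical ROC curves with trapezoidal AUC,
    Spearman rank correlation with interpretation bands), strict CSV
    cohort input/output with row-level validation, a seeded synthetic
    cohort simulator with a logistic one-year mortality model and a
    latent-linear Katz model, and an end-to-end analysis pipeline
    producing group comparisons, mortality ROC, score-Katz correlation
    with early-death exclusion, and age-band score decompositions.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
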