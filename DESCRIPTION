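Package: glycohazard
Title: Discrete-Time Hypoglycemia Hazard Modelling for ICU Cohorts
Version: 0.1.0
Authors@R:
    person("Glycohazard", "Developers", email = "glycohazard@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the association between body-mass index and
    hypoglycemia in intensive-care cohorts. Implements hypoglycemia episode
    detection with a six-hour termination rule, time-weighted average glucose
    and glycemic-variability summaries, rule-based covariate engineering
    (bounded carry-forward imputation, shock flags, insulin and dextrose dose
    normalisation, hourly SOFA scoring), construction of a discrete-time
    six-hour-window hazard dataset censored at first hypoglycemia, pooled
    logistic regression with odds ratios, generalized variance-inflation
    factors and likelihood-ratio tests, bootstrap group summaries, and a
    synthetic ICU-cohort generator with known ground-truth hazard
    coefficients for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
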