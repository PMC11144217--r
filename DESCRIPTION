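Package: gpadelta
Title: Genomically Predicted Achievement Discrepancies in Twin Cohorts
Version: 0.1.0
Authors@R:
    person("gpadelta", "maintainers", email = "maintainers@gpadelta.invalid",
           role = c("aut", "cre"))
Description: Tools for quantifying academic under- and over-achievement as the
    discrepancy between standardized observed achievement and standardized
    genomic prediction (a polygenic score), and for charting how those
    discrepancies evolve across the school years. Provides a synthetic
    twin-cohort generator with ACE covariance structure and an age-varying
    polygenic-score validity, discrepancy-score construction (difference and
    residualized forms), per-individual achievement slopes with median-absolute-
    deviation outlier filtering, regression-toward-prediction summaries with
    trimmed means, relative/absolute achiever group classification and decile
    trajectories, hierarchical regression with semi-partial R-squared and nested
    F tests, SES moderation, repeated cross-validated multi-score weighting with
    variance-inflation diagnostics, dependent-correlation comparison, univariate
    twin ACE maximum-likelihood fitting with profile-likelihood confidence
    intervals, and an end-to-end reproducible pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
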