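Package: adaptref
Title: Adaptive Reference Ranges for Longitudinal Biomarker Monitoring
Version: 0.1.0
Authors@R:
    person("adaptref", "maintainers", email = "maintainers@adaptref.dev",
           role = c("aut", "cre"))
Description: Personalised (adaptive) reference ranges for repeated biomarker
    measurements, updating as new observations accrue. Implements two
    complementary methods: a within-subject Student-t Z-score prediction
    interval built from a subject's own history, and a population-informed
    empirical-Bayes interval from a random-intercept linear mixed model with
    subject-specific residual variances, fitted by an
    expectation-maximisation algorithm. Includes a simulation toolkit for
    quantifying false-positive behaviour across grids of within- to
    between-subject variability ratios, a generator of
    inflammation-marker-like labelled series, and sensitivity/specificity
    evaluation machinery with alpha sweeps and a leave-one-subject-out
    protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
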