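Package: profilesim
Title: Monte-Carlo Evaluation of Risk-Adjustment Methods for Provider Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for assessing how well risk-adjustment
    methods classify outlying health-care providers. Generates synthetic
    cardiac-surgery-style cohorts with confounded provider assignment,
    draws in-hospital mortality from a random-intercept logistic model with
    a configurable outlier structure, and applies six adjustment methods:
    fixed- and random-effects logistic regression, generalized propensity
    score (gPS) adjustment, gPS inverse-probability weighting with and
    without trimming, and marginal mean weighting through stratification.
    Classification accuracy (sensitivity, specificity, PPV, NPV, eagerness)
    is summarised over replicates with 90th-percentile intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
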