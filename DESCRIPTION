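Package: btcea
Title: Cost-Effectiveness Modelling of Bronchial Thermoplasty and Omalizumab in Severe Allergic Asthma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A probabilistic decision-analytic Markov cohort model comparing
    standard therapy, bronchial thermoplasty, and omalizumab for
    moderate-to-severe allergic asthma. Implements a five-state weekly-cycle
    cohort engine with discounted costs and quality-adjusted life years,
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves and expected value of perfect information, deterministic one-way
    and threshold sensitivity analyses, and the random-effects meta-analysis
    machinery (including borrowed between-study variance) used to derive
    treatment relative rates. Inputs and outputs are tidy tibbles; results
    carry broom-style tidy() and glance() methods and ggplot2 plotting
    helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
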