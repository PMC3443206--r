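Package: aafsurvey
Title: Average Attributable Fractions for Co-Morbid Chronic Conditions in
    Complex Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the respective contribution of co-morbid chronic
    conditions to disability in complex cross-sectional surveys. Provides a
    full survey weighting chain (design weights, logistic non-response
    propensity adjustment, raking calibration), disability classification
    from the six Katz activities-of-daily-living items, gross attributable
    fractions by Levin's formula with log-complement confidence intervals,
    and covariate-adjusted survey-weighted average attributable fractions
    (the Shapley decomposition of the joint attributable fraction over
    elimination orders) with expected prevented-case counts. Includes a
    synthetic survey generator with a known disability-generating model and
    a ground-truth oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
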