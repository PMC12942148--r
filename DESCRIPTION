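Package: effortlens
Title: Detecting Non-Effortful Respondents with Response Times and Person Fit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for identifying non-effortful (rapid-guessing) respondents
    in low-stakes assessments from item responses and response times. Implements
    the Snijders-corrected standardized log-likelihood person-fit statistic
    (lz*) under the two-parameter logistic model with maximum-likelihood
    ability estimation, marginal maximum likelihood (Bock-Aitkin EM) item
    calibration, response-time based K-means and self-organizing-map
    clustering of respondents, and a two-step procedure that purifies the
    calibration sample by clustering before computing lz*. Includes a
    hierarchical response/response-time simulator with an injectable
    rapid-guessing mixture and a factorial Monte-Carlo experiment runner
    scoring recall, precision, F1 and item-parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
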