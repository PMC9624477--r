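Package: qbamisclass
Title: Validation-Based Quantitative Bias Analysis for Misclassified Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and adjusting for misclassification of a
    binary health outcome ascertained from an error-prone classifier such as a
    diagnostic code in the electronic health record. Estimates sensitivity,
    specificity, predictive values and their complements from an internal
    validation subcohort via logistic regression (with bootstrap confidence
    intervals and a likelihood-ratio test for differential misclassification),
    propagates the estimated accuracy parameters through probabilistic
    (Monte Carlo) bias analysis to obtain misclassification-adjusted prevalence
    and relative-risk distributions, provides the closed-form bias theory for
    nondifferential misclassification, relative-risk estimation by modified
    Poisson regression with robust variance, and a synthetic cohort generator
    with known truth for end-to-end verification.
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
    MASS,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
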