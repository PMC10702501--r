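Package: dcebr
Title: Benefit-Risk Discrete Choice Experiments for Treatment Preferences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing benefit-risk
    discrete choice experiments (DCEs) of the kind used to elicit treatment
    preferences of patients with relapsed/refractory multiple myeloma.
    Provides D-efficient choice-task design by coordinate exchange with
    blocking and internal-validity (stability and dominance) tasks, a
    synthetic-respondent simulator driven by an error-component random
    utility model, maximum simulated likelihood estimation of the
    error-component logit with scrambled Halton draws, relative attribute
    importance (RAI) scores with Krinsky-Robb confidence intervals,
    minimal-acceptable-benefit (MAB) trade-off calculations on the overall
    response rate and overall survival scales, subgroup heterogeneity via
    attribute-by-covariate interactions, and an end-to-end reporting
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
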