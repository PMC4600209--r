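Package: rehabrank
Title: Ranking Home-Care Assessment Items That Predict Rehabilitation Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying which items of a standardized home-care
    assessment best predict whether a client goes on to receive
    rehabilitation services. Implements frequency-matched stratified
    resampling against a target joint distribution over five matching
    variables (age band, gender, ADL impairment, cognition, falls),
    variable ranking by order of entry along a group-lasso penalized
    logistic solution path, permutation-based variable importance from a
    random forest, ensemble aggregation of ranks over repeated matched
    samples, and a configurable decision-tree scorer for the expert-derived
    Contact Assessment rehabilitation algorithm. A synthetic-cohort
    generator with planted logistic effects and interactions stands in for
    confidential clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr,
    ranger,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
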