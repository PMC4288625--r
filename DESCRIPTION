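Package: bprsig
Title: Blood Gene-Expression Diagnostic Signatures via Bayesian Probit
    Regression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and validates diagnostic gene-expression signatures
    from peripheral-blood microarray profiles. Provides Student-t feature
    ranking, two-metagene summarization by singular value decomposition
    with out-of-sample projection, Bayesian probit regression fitted with
    an Albert-Chib data-augmentation Gibbs sampler, fully nested
    leave-one-out cross-validation over signature sizes scored by ROC AUC
    and sum of deviance, Youden-index decision thresholds,
    validation-cohort performance reports, and a synthetic two-class
    cohort generator so the entire pipeline runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
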