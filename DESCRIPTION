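Package: grmmeans
Title: Group Mean Comparisons for Patient-Reported Outcomes Under the
    Graded Response Model
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for evaluating group mean comparison
    strategies for patient-reported outcome (PRO) measures: sum scores with
    Welch's t-test, multigroup graded-response-model (GRM) likelihood ratio
    tests, and expected-a-posteriori (EAP) trait scores with Welch's t-test.
    Includes a GRM data generator with item banks, directional differential
    item functioning (DIF), and missing-at-random responses; marginal
    maximum likelihood estimation of the multigroup GRM via an EM algorithm
    with fixed-node quadrature; an all-others-as-anchors likelihood-ratio
    DIF prescreening procedure with rank-based anchor selection; a Monte
    Carlo study runner computing Type I error, power, and effect-size mean
    absolute error; and shallow regression-tree summaries of the resulting
    condition tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    truncnorm,
    numDeriv,
    optparse
Config/testthat/edition: 3
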