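Package: corovpc
Title: Virtual Patient Cohorts and Correlated Sensitivity Analysis for Coronary FFR
Version: 0.1.0
Authors@R:
    person("VPC", "Maintainers", email = "maintainers@corovpc.org", role = c("aut", "cre"))
Description: Generates synthetic virtual patient cohorts of multi-vessel coronary
    artery disease with a reduced-order pulsatile model of the coronary
    circulation, computes per-lesion fractional flow reserve (FFR), filters
    cohorts by physiological acceptance criteria, recovers filter-induced input
    correlations with a Gaussian copula, trains kernel greedy (VKOGA) surrogate
    models of FFR, and estimates the five correlated variance-based sensitivity
    indices (S^TC, S^TU, S^U, S^C, S^IU) on Smolyak sparse grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
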