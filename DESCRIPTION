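Package: stepbma
Title: Simulation Comparison of Bayesian Model Averaging and Stepwise
    Variable Selection in Linear Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo machinery for studying the operating
    characteristics of automatic variable-selection procedures in linear
    regression. Implements Bayesian model averaging with
    BIC-approximated posterior model probabilities, Occam's window and
    per-variable posterior inclusion probabilities, alongside forward
    stepwise selection by AIC with a p-value exclusion step. Ships a
    simulation engine for five data-generating processes with 20
    candidate predictors (including correlated-redundant and
    indirect-predictor constructions), paired application of all
    selectors to identical datasets, and estimation of selection
    probabilities (true predictor selected, redundant variable avoided,
    exactly correct model) with binomial standard errors across a grid
    of noise levels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
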