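Package: ssglv
Title: Spike-and-Slab Bayesian Inference of Generalized Lotka-Volterra
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and Bayesian inference for microbial consortium
    dynamics under discrete-time stochastic generalized Lotka-Volterra
    (gLV) models. Generates measurement-realistic abundance time series
    for inoculum-knockdown experimental designs, infers the microbe-microbe
    interaction network with a spike-and-slab Gibbs sampler (Bernoulli edge
    indicators, conjugate Gaussian coefficients, scaled inverse-chi-squared
    variances), reports per-edge Bayes factors with the conventional 3/10
    evidence thresholds, and computes ecological summaries: Pielou
    evenness, log-fold knockdown ratios, and four-parameter logistic EC50
    growth-requirement fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
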