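Package: efttrial
Title: Phase I-II Efficacy-Toxicity Trade-Off Designs with Copula Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for Bayesian phase I-II dose-finding trials
    that jointly model a binary toxicity and a binary efficacy endpoint.
    Implements three joint probability models for the bivariate binary
    outcome (the Arnold-Strauss exponential-family copula used by Braun, the
    Gumbel-Morgenstern copula used by Thall and Cook, and an independence
    working model), logistic dose-response marginals, an adaptive
    Metropolis-within-Gibbs sampler for posterior inference, the
    acceptability/desirability trade-off dose-finding algorithm, and
    Monte-Carlo evaluation of design operating characteristics under correct
    and misspecified joint models, including correlation-estimability
    studies and sample-size/prior sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
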