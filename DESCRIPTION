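Package: winodds
Title: Covariate-Adjusted Win Odds for Hierarchical Composite Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation and inference for the win odds in two-arm randomized
    trials with hierarchical composite time-to-event endpoints (e.g. death
    then first nonfatal event). Implements the direct (unadjusted) estimator
    with two-sample U-statistic inference, and covariate adjustment through
    the marginal probabilistic index: a probabilistic index model with logit
    link is fitted on all n(n-1) pairwise pseudo-observations, standardized
    over the empirical covariate-pair distribution, and equipped with a
    projection (Hajek) sandwich variance. Includes a latent failure-time
    simulator with empirical-quantile censoring and an operating-
    characteristics runner for type I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
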