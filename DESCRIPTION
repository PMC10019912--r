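Package: cbctrends
Title: Century-Scale Wintering-Bird Population Dynamics from Christmas
    Bird Count-Style Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating long-term avian population trajectories
    from single-visit winter count surveys with variable and partially
    unrecorded sampling effort. Provides a synthetic data generator for
    Christmas Bird Count-like panels, per-circle imputation of sampling
    effort (gamma-shaped trend curves before 1967, local regression
    afterwards) with prediction-interval uncertainty, a Bayesian
    single-visit Dail-Madsen open-population N-mixture model fitted by a
    Metropolis-within-Gibbs sampler over latent abundances with effort
    measurement error, Gelman-Rubin convergence diagnostics, GAM-based
    trend smoothing with 3-year first-derivative extraction and run-length
    non-stationarity classification, k-medoids (PAM/CLARA) clustering of
    standardized trend curves, and per-circle cluster-composition
    summaries with chi-square dominance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    mgcv,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    coda,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
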