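Package: dsemrt
Title: Dynamic Structural Equation Modeling of Trial-Level Reaction Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a two-level dynamic structural equation model (DSEM) of
    trial-level reaction time in which every person carries their own mean
    level, lag-1 autoregression, linear practice trend, and residual variance
    (the latter on a log-linear scale), and the four person-specific
    components are predicted by white-matter fractional anisotropy and age.
    Estimation is by a Gibbs-within-Metropolis MCMC sampler with joint
    modeling of partially missing exogenous covariates. Includes a synthetic
    cohort generator emulating a two-stage lifespan study, convergence
    diagnostics (potential scale reduction, iteration-doubling relative-bias
    protocol), deviance information criterion model comparison, posterior
    summaries (standardized effects, between-person R-squared, factor scores,
    posterior-SE p-values with false discovery rate correction), and the
    comparison of model-based variability with observed intraindividual SD
    and coefficient of variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
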