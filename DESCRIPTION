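Package: occubayes
Title: Bayesian Single-Season Occupancy Models and Richness GLMs for
    Winter Wetland Bird Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits single-season site-occupancy models with imperfect
    detection to replicated detection/non-detection point-count data,
    using a data-augmented Metropolis-within-Gibbs sampler with logistic(0, 1)
    priors on all coefficients. Provides global-to-reduced covariate
    selection via 50% credible intervals, model comparison by the widely
    applicable information criterion (WAIC), split-chain Gelman-Rubin
    convergence diagnostics, derived occupancy probabilities and
    log-odds-ratio curves, a Poisson log-linear model of apparent avian
    species richness, and a synthetic-data generator that emulates a
    two-year winter wetland survey design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    rjags,
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
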