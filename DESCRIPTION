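Package: jawrates
Title: Macroevolutionary Consequences of the Jaw Velocity-Force Trade-Off
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-methods pipeline for testing whether biomechanical
    specialization along the jaw velocity-force trade-off acts as an
    asymmetrical constraint on craniofacial evolution. Computes lower-jaw
    mechanical advantage from lever measurements, removes allometry with
    phylogenetic (generalized least squares) residuals, relates shape axes to
    mechanical advantage with PGLS, contrasts morphological disparity between
    velocity- and force-modified jaws with a permutation test over a gradient
    of percentile cut-offs, and fits a Bayesian state-dependent multivariate
    Brownian-motion rate model with stochastic character mapping and
    compound-Poisson background rate variation (MuSSCRat-style) by MCMC.
    Includes a synthetic-data generator with the same generative structure so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    optparse
Config/testthat/edition: 3
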