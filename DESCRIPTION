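Package: mthess
Title: Multi-Tissue Hierarchical Evolutionary Stochastic Search for eQTL Hotspot Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian hierarchical sparse regression for jointly mapping
    associations between many predictors (e.g. SNPs) and many responses
    (e.g. gene expression) measured in several conditions or tissues.
    Implements the multi-tissue HESS model: per-response matrix-variate
    regressions with a g-prior on effects, a multiplicative
    hotspot-propensity decomposition of the selection probabilities, and
    an Evolutionary Monte Carlo sampler over tempered chains.
    Post-processing provides marginal posterior probabilities of
    inclusion, Bayesian FDR thresholding, hotspot tables, re-normalized
    model probabilities and leave-one-out model-adequacy checks.
    Includes a recombinant-inbred-panel simulator and an evaluation
    harness with MANOVA and single-tissue baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
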