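Package: connlda
Title: Latent Disease Factor Modelling of Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Dana", "Reyes", email = "dana.reyes@example.org", role = c("aut", "cre"))
Description: Decomposes whole-brain functional-connectivity data into a small
    number of co-expressed latent disease factors using a hierarchical
    Bayesian model (latent Dirichlet allocation over signed connectivity
    deviation counts), fitted by variational EM. Provides out-of-sample
    estimation of factor expression in unseen individuals, bootstrap
    edge-wise significance of factor connectivity profiles with false
    discovery rate control, permutation-tested canonical correlation
    between factor expression and item-level clinical scores with
    site-aware permutation, individual-level Dice overlap between a
    subject's top-weighted edges and a factor's significant profile, and a
    synthetic-cohort generator that plants known factor structure so every
    stage of the pipeline can be validated without access to restricted
    neuroimaging cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
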