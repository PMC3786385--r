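Package: traitpaths
Title: Hypercubic Pathway Inference for Binary Trait Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian inference of evolutionary trajectories of binary trait
    accumulation on a hypercubic phenotype landscape. Species are scored as
    phenotype strings (trait absent/present/missing), and an ensemble
    hidden-Markov likelihood connects observed intermediate phenotypes to
    weighted monotone transition networks on the L-trait hypercube.
    Metropolis MCMC over edge weights yields posterior acquisition-order
    summary matrices, missing-trait predictions with occlusion validation,
    contingent-acquisition tables, and an exact search for single
    deterministic orderings. Includes mixture-model and hierarchical
    binarization of quantitative trait tables, PCA with EM imputation, and
    synthetic dataset generators for validation. Motivated by the convergent
    evolution of C4 photosynthesis from C3 ancestors via C3-C4 intermediates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
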