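Package: bayestfm
Title: Regularized and Bayesian Traction Force Microscopy Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs cellular traction stresses from measured substrate
    displacements on linear elastic half-space substrates (traction force
    microscopy). Provides the Boussinesq forward model on regular traction
    grids with fast Fourier assembly and shift-theorem support for
    irregularly sampled displacement data, five regularized inverse solvers
    (Tikhonov/L2, Lasso/L1, Elastic Net, and proximal-gradient wavelet
    variants), classical parameter selection by the L-curve criterion and
    generalized cross validation, and two parameter-free Bayesian solvers
    that select the L2 regularization level by evidence maximization.
    Includes a synthetic-scene generator with analytic disc displacements
    and four reconstruction-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
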