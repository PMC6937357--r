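Package: petiq
Title: Simulation and Image-Quality Analysis of Penalized-Likelihood PET Reconstruction
Version: 0.1.0
Authors@R:
    person("petiq", "developers", email = "petiq@example.org", role = c("aut", "cre"))
Description: Digital-phantom simulation and quantitative image-quality analysis
    for whole-body PET under low-count conditions. Provides voxelized NEMA NU2
    image-quality and micro hollow-sphere phantoms, a Poisson acquisition
    simulator with attenuated parallel-beam projection, triangular axial
    sensitivity and overlapping bed positions, reconstruction by ordered-subset
    expectation maximization (with and without resolution modelling) and by
    block sequential regularized expectation maximization with a relative
    difference penalty, and the standard image-quality metrics: 50%-isocontour
    recovery coefficients, background variability, residual lung error,
    per-slice coefficient of variation profiles and noise-versus-counts fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
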