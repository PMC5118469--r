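Package: rkcca
Title: Regularized Kernel Canonical Correlation Analysis for Two or More Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Canonical correlation analysis (CCA) between two or more
    numeric timeseries datasets, solved as a regularized block generalized
    eigenvalue problem in either the primal (covariance) or dual (kernel)
    formulation, with linear, Gaussian and polynomial Gram matrices.
    Includes cross-dataset prediction of held-out samples through a
    spectral-cutoff pseudoinverse of the canonical weights, per-component
    explained variance in held-out data, asymptotic significance testing of
    prediction correlations with false discovery rate control,
    hyperparameter selection by Monte-Carlo block cross-validation over a
    regularization-by-components grid, a latent-variable synthetic data
    generator for end-to-end validation, and HDF5 model persistence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
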