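Package: spaduav
Title: Winter Wheat SPAD Prediction from UAV-Style Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for estimating winter wheat
    relative chlorophyll content (SPAD) from multispectral canopy imagery.
    Generates synthetic 72-plot field scenes with a known SPAD-to-reflectance
    forward model, simulates higher flight altitudes by nearest-neighbor
    resampling of the ground sampling distance, extracts vegetation indices,
    gray-level co-occurrence (Haralick) texture features and single-level
    biorthogonal 1.3 wavelet features per plot, selects variables by
    cross-validated recursive feature elimination with a random-forest
    estimator, fits ridge, random-forest, support-vector and neural-network
    regressions with grid-searched hyperparameters, and evaluates models with
    R2, RMSE, relative RMSE and the ratio of performance to deviation across
    altitude and variable-set grids.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    glmnet,
    e1071,
    nnet,
    jsonlite,
    rlang,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
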