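Package: specbrix
Title: Wavelength Selection and Regression for Fruit Soluble-Solids Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric pipeline for predicting fruit soluble solid content
    (SSC, degrees Brix) from visible/near-infrared reflectance and fluorescence
    emission spectra. Provides a synthetic spectra generator with a known
    SSC-to-spectrum forward model, spectral pre-processing (SNV, detrend,
    Savitzky-Golay, Gaussian/boxcar/exponential smoothing, black-and-white
    calibration, effective-band cropping), Kennard-Stone sample partitioning,
    five model-population-analysis wavelength selectors (Boss, CARS, IVSO,
    IVISSA, MASS) plus secondary Boss cascades built on a shared PLS
    cross-validation engine, three regression models (PLSR, extreme learning
    machine, least-squares SVM tuned by particle swarm optimisation), and
    R2/RMSE/RPD evaluation with a configurable benchmark grid.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    MASS,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
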