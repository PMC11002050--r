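Package: nutrispec
Title: Nutrient Quantification from Mid-Infrared Photoacoustic Spectra with
    Tolerance-Interval Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for predicting macro- and micro-nutrient
    concentrations in manure and digestate from Fourier-transform infrared
    photoacoustic (FTIR-PAS) spectra. Provides a seeded synthetic spectra
    generator (Gaussian-copula concentration sampling and Beer-Lambert style
    band mixing), mean-centering and multiplicative scatter correction,
    NIPALS partial least squares regression with leave-one-out
    cross-validation for latent-variable selection, stratified train/test
    splitting, and three assessment criteria: conventional statistics (RMSE,
    R-squared, RPD), Z-score Shewhart control charts, and an error-tolerance
    interval method that classifies each prediction as inside or outside a
    policy-derived acceptable band.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
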