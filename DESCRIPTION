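Package: scfavolt
Title: Voltammetric Fingerprinting and Neural-Network Calibration of Fecal
    Short-Chain Fatty Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies propionate, butyrate, and total short-chain fatty
    acids (SCFAs) from differential pulse and cyclic voltammetry
    fingerprints. Provides trace I/O and validation, baseline-corrected
    descriptor extraction (characteristic currents, potentials, and windowed
    areas), leakage-free min-max scaling, a from-scratch multilayer
    perceptron with cross-information and hierarchical input designs,
    multiple linear regression and random forest baselines, mass-balance
    acetate estimation, and a full method-agreement suite (MAE/RMSE/R2,
    threshold agreement, Bland-Altman limits, bootstrap confidence
    intervals, paired tests, five-fold cross-validation). A seeded synthetic
    voltammogram generator anchored to published standard-mixture
    calibrations, with a configurable fecal-matrix distortion model,
    supports end-to-end testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
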