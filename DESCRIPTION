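Package: uirsim
Title: Bottom-Up Simulation of ATR-FTIR Urine Spectra and Chemometric
    Model Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates attenuated total reflectance Fourier-transform
    infrared (ATR-FTIR) absorbance spectra of liquid urine as linear
    mixtures of pure-component standard spectra plus water and
    instrument noise, and provides the chemometric stack needed to
    optimize a urinary albumin/creatinine (UACR) assay entirely in
    silico: seven-level mutually orthogonal calibration designs,
    simulated protein preconcentration and cleaning-step pretreatment,
    spectral preprocessing (weighted least-squares baseline, standard
    normal variate, Savitzky-Golay derivative, mean centering), NIPALS
    partial least squares regression and discriminant analysis,
    venetian-blinds and Monte Carlo double cross-validation, and model
    diagnostics (regression vectors, VIP scores, orthogonalized
    loadings).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
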