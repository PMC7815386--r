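Package: nirchemo
Title: Chemometric Modelling of FT-NIR Spectra for Herbal Quality Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete chemometrics workflow for Fourier-transform
    near-infrared (FT-NIR) absorbance spectra of powdered herbal materials:
    simulation of Beer-Lambert mixture spectra with scatter, baseline and
    noise artefacts; spectral pretreatments (multiplicative scatter
    correction, standard normal variate, Savitzky-Golay derivatives);
    deterministic SPXY / Kennard-Stone calibration-set selection;
    geographic-origin classification with a grid-searched RBF-kernel support
    vector machine; NIPALS partial least squares regression with the usual
    calibration diagnostics (R2C, R2P, RMSEE, RMSECV, RMSEP, RPD); synergy
    interval PLS wavenumber selection; and external-standard HPLC reference
    arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
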