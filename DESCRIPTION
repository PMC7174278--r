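Package: granudry
Title: In-Line NIR Monitoring of Fluidised-Bed Granule Drying
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Chemometric process analytics for fluidised-bed drying of
    pharmaceutical granules monitored by an in-line near-infrared sensor.
    Provides spectral preprocessing (block averaging, absorbance transform,
    causal moving average, standard normal variate), NIPALS partial least
    squares regression of log moisture content with cross-validated latent
    variable selection, PCA-based multivariate statistical process control
    with Q-statistic charts and Jackson-Mudholkar control limits for drying
    end-point detection, GAB sorption isotherm utilities, and a
    mass-transfer-resistance analysis of the drying kinetics. A synthetic
    batch generator forward-simulates moisture and bed-temperature
    trajectories from the resistance model and emits realistic noisy spectra
    and sparse loss-on-drying samples so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
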