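Package: fetox
Title: Multi-Layer Self-Calibrated Transabdominal Fetal Pulse Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of fetal arterial oxygen saturation (SpO2) from
    transabdominal near-infrared spectroscopy. Implements a self-calibrated
    spectral-fitting algorithm in both its single-layer (semi-infinite mean
    pathlength) and multi-layer form, the latter built on an analytical
    N-layer diffusion model of photon partial pathlengths. Includes a layered
    slab Monte-Carlo photon transport validator with pathlength-rescaled
    absorption, spectrogram/ridge extraction of the fetal pulsatile component
    from mixed maternal-fetal intensity time series, virtual-subject cohort
    simulation, and robustness evaluation utilities (cleaning, error metrics,
    parameter-perturbation studies, baseline property calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
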