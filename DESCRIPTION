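Package: faruvc
Title: Far-UVC Skin Dosimetry, Radiative Transfer and Reflectance Colorimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for far-UVC (222 nm krypton-chloride lamp)
    skin-safety studies. Reads and manipulates lamp emission spectra, computes
    radiant exposures and ICNIRP actinic-hazard quantities, estimates
    germicidal log-reduction times for packaged coronavirus susceptibility
    constants, runs Monte Carlo radiative transfer through a five-layer skin
    model to obtain depth- and wavelength-resolved fluence rates, converts
    reflectance spectra to CIELAB and tracks irradiation-induced changes in
    redness (delta a*) and yellowness (delta b*), and generates synthetic lamp
    spectra, skin optics and reflectance time series with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
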