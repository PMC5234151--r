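Package: nirfat
Title: Monte Carlo Simulation of Near-Infrared Reflectance for Subcutaneous
    Fat Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating near-infrared (NIR) diffuse reflectance of
    layered skin models for neonatal body-fat sensing. Layer absorption is
    composed from chromophore volume fractions (water, fat, blood, melanin plus
    an intrinsic baseline), reduced scattering follows a power law in
    wavelength, and photon transport through the layer stack is computed by a
    weighted Monte Carlo kernel with Fresnel boundaries and an angled
    fibre-source / cosine-corrector detector geometry. Experiment drivers
    produce fat-thickness response curves with their per-mm sensitivity and
    logarithmic fits, reflection spectra across skin colour and hydration
    states, and hydration-window reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
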