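Package: subdrs
Title: Subdiffusive Diffuse Reflectance of Bilayer Media with Tilted Fiber Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com", role = c("aut", "cre"))
Description: Forward Monte Carlo modelling and look-up-table inversion of
    sub-diffusive diffuse reflectance measured with multi-fiber probes that use
    tilted, beveled optical fibers. Photon transport in layered turbid media
    (oil film, finite top layer, semi-infinite deep layer) is simulated with a
    white Monte Carlo scheme that stores per-layer partial path lengths so any
    absorption coefficient can be applied afterwards through Beer-Lambert
    reweighting. The package builds gridded reflectance look-up tables over
    (reduced scattering, the gamma similarity parameter, absorption) for one or
    two layers plus the interface depth, inverts noisy per-fiber-combination
    reflectance by exhaustive grid search with uncertainty propagation, models
    the spectrometer signal chain (bias, dark/ambient drift, temporal and
    intensity nonlinearities, Savitzky-Golay smoothing) and jointly estimates
    the per-combination calibration coefficient and per-phantom gamma from
    integrating-sphere referenced phantom measurements. Synthetic-data
    generators reproduce the noise, thickness, contrast and fiber-count
    characterization studies at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
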