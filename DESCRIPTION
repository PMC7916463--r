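Package: photoseed
Title: Photothermal Simulation of Plasmonic Nanocomposite Implant Thermotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coupled optical-thermal-damage modelling of near-infrared
    laser-heated plasmonic nanocomposite implants (photoseeds) in breast
    tissue. Builds voxelized multi-layer tissue phantoms with implanted
    photoseed arrays, computes continuous-wave fluence fields under the
    optical diffusion approximation, time-integrates the Pennes bioheat
    equation with temperature-dependent conductivity and damage-dependent
    blood perfusion, and accumulates Arrhenius thermal-damage fields with
    lesion metrics. Also implements the bench-side photothermal calorimetry
    analysis (initial heating rate, Roper conversion efficiency, trypan-blue
    viability arithmetic) and deterministic synthetic-data generators for
    IR-camera-like heating curves and toy phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
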