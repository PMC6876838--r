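Package: minibeam
Title: Dose Modelling and Tissue-Response Analysis for Proton Pencil Minibeam Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatially fractionated proton minibeam radiotherapy
    studies: analytic dose modelling of Gaussian pencil-beam lattices
    (peak-to-valley dose ratio, diagonal profile cuts, beam-width fitting),
    particle-counting fluence dosimetry with dead-time correction,
    depth-dependent lateral beam spread via Fermi-Eyges integration of the
    Highland scattering formula with Bragg-Kleeman range-energy mapping,
    linear-quadratic clonogenic survival averaged over the lattice unit
    cell, and analysis of longitudinal skin-response and ear-swelling
    measurements including linear extrapolation of the no-effect beam-size
    threshold. A calibrated synthetic-data generator emulates the in-vivo
    measurement campaign so that every pipeline stage is testable without
    animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
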