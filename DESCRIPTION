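Package: retistim
Title: Multi-Scale Modelling of Transcorneal Electrical Stimulation of the Retina
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale multi-scale simulation of transcorneal electrical
    stimulation (TES) of the rat retina. Builds a voxelized head-eye volume
    conductor solved by the admittance (resistor network) method, couples the
    extracellular potentials to multi-compartment conductance-based models of
    a spiking DB4 bipolar cell and an A2 retinal ganglion cell, and provides a
    threshold engine (strength-duration curves, electrode-placement threshold
    ratios) together with a Shannon electrode-safety calculator for the
    corneal ring electrode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
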