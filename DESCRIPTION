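Package: acsim
Title: Event-Driven Simulation of the Approach Sensitivity Retinal Ganglion Cell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulator of the Approach Sensitivity Cell (AC), a
    retinal ganglion cell type that fires for expanding (approaching) objects.
    Works directly on Address-Event-Representation (AER) streams from a
    128x128 Dynamic Vision Sensor: reads and writes jAER-style AEDAT 2.0
    binary files and a plain CSV dialect, synthesizes DVS event streams from
    parametric looming/receding/translating stimuli, denoises streams with
    background-activity and hot-pixel filters, runs the AC model (ON/OFF
    subunit grid, half rectification, center-surround suppression,
    integrate-and-fire or Poisson firing, periodic shared decay), and
    quantifies response determinism across stimulus repetitions with a
    Shannon-entropy analysis and inter-spike-interval statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
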