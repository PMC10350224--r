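Package: duofoci
Title: Simulation and Planning Toolkit for Dual-Foci Axially Swept
    Light-Sheet Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the computational core of a dual-foci axially swept
    light-sheet microscope: rolling-shutter exposure scheduling for single-
    and dual-shutter sCMOS acquisition, sawtooth actuator drive waveforms
    with flyback, actuator tracking and synchronization-error maps, noisy
    image formation on synthetic bead phantoms, Gaussian-beam and
    multi-immersion optical scaling, point-spread-function FWHM
    quantification with Richardson-Lucy deconvolution, intensity-based and
    convolutional-network triage of informative tissue tiles, and tiled
    acquisition time and storage budgeting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    yaml,
    minpack.lm,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
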