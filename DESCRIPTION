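Package: photoacid
Title: Simulation and Analysis of Optogenetically Induced Intracellular
    Acidification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying intracellular acidification caused by
    proton flux through light-gated cation channels (channelrhodopsins).
    Provides a mechanistic forward simulator of a single well-mixed cellular
    compartment under interleaved optogenetic stimulation and fluorescence pH
    imaging (opsin photocurrent, membrane voltage, proton flux against
    cytosolic buffering, pH-sensor fluorescence with photoartifact and noise),
    a gap-junction-coupled monolayer simulator for patterned-illumination
    experiments, the full image-to-kinetics analysis pipeline (epoch
    collapsing, ROI delta-F/F extraction, photoartifact subtraction,
    piecewise-linear pH calibration, acidification half-times, exponential
    recovery fits, nonparametric group statistics), and photocurrent
    characterization (EPD50, gating time constants, reversal potential,
    action spectra, imaging-light crosstalk, Nernst selectivity shifts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
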