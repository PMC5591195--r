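Package: smSweep
Title: Spatially Encoded Fast Single-Molecule Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, decoding and kinetic analysis of mirror-swept
    single-molecule fluorescence movies. Stepping a galvo mirror N times
    during one camera exposure spreads each molecule into N laterally
    offset spots, encoding sub-frame temporal information in the spatial
    domain. The package simulates such EMCCD movies from two-state kinetic
    models (photoblinking, transient DNA binding, two-state FRET), decodes
    swept spots back into sub-frame-resolution intensity traces
    (spot detection, bead-based channel mapping, sliding-window
    extraction, overlap filtering), and implements the downstream kinetic
    analyses: blinking autocorrelation with a two-state fit, threshold
    dwell-time extraction with exponential maximum likelihood, FRET
    efficiency with background and leakage correction, and two-state
    Gaussian hidden Markov rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
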