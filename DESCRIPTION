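Package: speller3d
Title: Simulation and Analysis of 2D Row-Column and 3D Column-Only P300
    Speller Paradigms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end simulation and analysis pipeline for P300 speller
    brain-computer interfaces. Generates flashing schedules for the
    classical 2D row-column paradigm and a 3D column-only paradigm in
    which the character grid is transposed halfway through a run,
    synthesizes multichannel EEG with P300 deflections time-locked to
    target flashings over 1/f background noise, preprocesses the signals
    (band-pass filtering, epoching, baseline correction, repetition
    averaging), detects P300 responses with a two-layer neural network
    trained by cross-entropy minimization, decodes spelled characters,
    and summarizes performance with classification accuracy, the
    radar-polygon area statistic (ACRC), and paired significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
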