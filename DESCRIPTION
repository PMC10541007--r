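Package: songpeth
Title: Mouse Ultrasonic Song Segmentation and Event-Triggered Neural Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing courtship ultrasonic vocalization (USV)
    behaviour together with simultaneously recorded neural signals. Parses
    USV syllables and songs from high-bandwidth audio by spectrogram
    binarization and neighbourhood cleaning; computes fiber-photometry
    delta-F/F, song-onset-triggered averages with random-trigger permutation
    bands, and calcium onset times by 10-90% line-fit extrapolation; detects
    threshold-crossing spikes after common-median referencing, builds
    peri-event time histograms and permutation-based responsiveness tests;
    and contrasts Song-Inducing against Quiet social exposures per unit
    (delta-PETH) with a label-shuffle null. A synthetic-session generator
    with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
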