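Package: avechr
Title: Algorithm-Supported Visual Error Correction for Beat-to-Beat Heart Rate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cleaning beat-to-beat heart-rate recordings with pronounced
    respiratory sinus arrhythmia, as found in dogs monitored with chest-belt systems.
    Implements a windowed outlier criterion with a confidence-level-derived threshold
    multiplier (after Graf and Henning), a single-pass detection scan with
    most-extreme-first resolution of overlapping candidate windows, correction by
    deletion or local mean replacement with a replayable edit log that never inserts
    values, time-domain heart-rate-variability summaries (SDNN, RMSSD, pNN50),
    a perturbation experiment contrasting deletion with mean replacement, a synthetic
    generator of canine-like RR series with labelled transmission artifacts, block
    plots for visual inspection, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
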