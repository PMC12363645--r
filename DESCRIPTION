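Package: periboot
Title: Post Hoc Resampling Statistics for Peri-Event Fiber Photometry
    Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unbiased post hoc statistics for peri-event fiber photometry
    time series arranged as group-per-sheet workbooks (one column per
    animal or trial, one row per timepoint). Provides per-timepoint
    bootstrapped confidence intervals with a small-sample narrowness
    adjustment, binary significance maps against a null of zero for
    baseline, between-subjects and within-subjects (paired) designs,
    consecutive-threshold run-length filtering of significance maps with a
    sensor-kinetics/low-pass threshold recommender, window-level
    permutation tests (label shuffling and paired sign-flipping), a
    block-mean downsampler, user-defined mean time bins, a seeded
    synthetic peri-event dataset generator, and a scriptable command-line
    interface that writes multi-sheet results workbooks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    readxl,
    stats,
    utils,
    withr,
    zip
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
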