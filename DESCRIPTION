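Package: semgforce
Title: Optimal sEMG Feature and Electrode-Site Selection for Grasp-Force
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for estimating hand grasp force from multi-channel
    surface electromyography (sEMG) and for selecting the smallest set of
    electrode measurement positions and time-domain features that still
    estimates well. Extracts variance (VAR), zero crossings (ZC),
    integrated EMG (IEMG) and Willison amplitude (WAMP) from sliding
    windows, enumerates every non-empty combination of measurement
    positions and features, estimates force with a general regression
    neural network (Gaussian kernel regression) under repeated
    action-wise train/test splits, scores each combination with
    range-normalized RMS and MAE errors and the Pearson correlation, and
    selects optimal combinations by one-way ANOVA followed by Tukey HSD
    homogeneous-subset grouping with a minimal-cardinality rule. A
    synthetic sEMG/force simulator with planted channel informativeness
    makes the whole pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
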