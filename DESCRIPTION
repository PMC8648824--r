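Package: tfcluster
Title: Cluster-Based Permutation Statistics for Cue-Conditioned EEG
    Time-Frequency Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multichannel EEG from probabilistically
    cued affective-stimulus experiments under a predictive-coding factorial
    model. Encodes stimulus intensity (INT), cued expectation (EXP) and
    absolute prediction error (PE = |EXP - INT|) factors over a 3x3
    cue-stimulus grid, builds probabilistic trial schedules, simulates
    synthetic oscillatory EEG and ordinal aversiveness ratings with known
    injected effects, computes sliding Hanning-window and multitaper
    time-frequency representations with z-score baselining, and performs
    mass-univariate repeated-measures linear-trend statistics with
    cluster-based Monte-Carlo permutation inference over channel x
    frequency x time, including spatial-neighbour cluster restriction and
    Bonferroni-corrected post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
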