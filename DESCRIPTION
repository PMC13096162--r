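Package: fibconn
Title: Fibonacci-Grammar Sequence Learning and Task-Driven Resting-State
    EEG Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying implicit sequence learning with the
    Fibonacci Lindenmayer grammar and its effect on directed resting-state
    EEG functional connectivity. Generates and inverse-parses grammar
    strings, annotates each position with its hierarchical ambiguity level,
    builds serial reaction-time sessions, and simulates cohorts with a
    continuous bilingualism score, trial-level reaction times, and
    vector-autoregressive multichannel recordings with known directed
    ground truth. Provides preprocessing (band-pass filtering, resampling,
    fixed-epoch segmentation, four-criterion artifact rejection, region-of-
    interest montage averaging), pairwise time-domain Granger causality
    with edge-list export, and penalized factor-smooth regression of edge
    strength on the bilingualism score with per-connection Wald tests,
    Benjamini-Hochberg false-discovery-rate correction, nested model
    comparison, and an end-to-end reproducible pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    signal,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
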