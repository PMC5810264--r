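Package: trialerp
Title: Single-Trial ERP Analysis Pipeline with Cluster Permutation Tests
    and Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Group-level EEG processing for single-trial event-related
    potential (ERP) analysis. Reads BrainVision recordings, performs
    deterministic preprocessing (average reference with recovery of the
    recording reference, zero-phase band-pass filtering, epoching,
    baseline correction, threshold/gradient artifact flagging), collects
    all trials of all participants into a 3-D trial store matched with
    behavioral metadata in original recording order, selects regions and
    time windows of interest with cluster-based permutation tests over
    channel-time adjacency, estimates ERPs by averaging or least-squares
    regression, exports per-trial region-of-interest amplitudes, and fits
    (generalized) linear mixed models with crossed participant and item
    random effects, sliding-difference contrasts, singular-term pruning,
    stepwise fixed-effect reduction and nested follow-ups. A ground-truth
    synthetic EEG/behavior generator makes every stage testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    MASS,
    methods,
    purrr,
    rhdf5,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
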