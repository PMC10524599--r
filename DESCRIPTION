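Package: afferent
Title: Spike-Train Timing and SNARE-Disassembly Kinetics for Hair-Cell
    Afferent Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses for loose-patch recordings of zebrafish lateral-line
    afferent neurons and for fluorescence-dequenching SNARE-disassembly
    assays. Implements spike detection in extracellular action-current
    traces, phase-locking statistics (per-cycle latency normalization,
    latency histograms with Gaussian fits, vector strength), spontaneous
    spike-timing analysis (interspike-interval statistics, recurrence maps
    and burst metrics with a permutation null, one- versus two-phase
    exponential model selection by the extra sum-of-squares F test,
    post-stimulus recovery curves), and initial-rate estimation with group
    comparison for plate-reader dequenching kinetics. Ships seeded
    phenomenological generators for every input class so each analysis
    stage is testable end to end.
License: MIT + file LICENSE
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
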