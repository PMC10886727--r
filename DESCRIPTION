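Package: phaseconn
Title: Phase-Based EEG Connectivity for Targeted Memory Reactivation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating phase-based functional connectivity (phase-locking
    value and weighted phase lag index) from epoched multichannel EEG in sliding
    analysis windows, with surrogate-data significance pruning, link-stability
    filtering, region-of-interest contrasts across pre-sleep, sleep and post-sleep
    sessions, sequence-specific behavioural skill metrics for serial reaction time
    tasks, and the repeated-measures and bootstrap statistics connecting them.
    Includes a synthetic-study generator that plants known phase-coupling structure
    and behavioural effects so the full pipeline can be validated against ground
    truth without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    boot,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
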