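Package: breathcog
Title: Respiration-Locked Cognition Analysis for Phase-Triggered Memory Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studies that lock cognitive events to the
    respiratory cycle. Detects inspiration/expiration onsets from nasal
    airflow recordings, emulates a closed-loop phase-triggered cue scheduler,
    projects task events onto the circular respiratory phase, classifies
    retrieval blocks by the phase transitions they span, computes
    signal-detection familiarity metrics (d-prime, criterion c), runs a
    repeated-measures statistical battery with assumption routing
    (Shapiro-Wilk/Mauchly, Greenhouse-Geisser, Friedman, Bonferroni post
    hocs, repeated-measures correlation), and builds first-level fMRI design
    matrices with phase-transition and respiration-volume-per-time (RVT)
    regressors. Includes a synthetic-data generator with planted behavioral
    effects so the full pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
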