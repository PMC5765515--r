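Package: uifscan
Title: Detection of Unexpected Increases in Frequency of Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens spontaneous adverse-event report databases for unexpected
    increases in frequency (UIF) of monthly report counts per drug-event
    combination. The detector fits a negative binomial log-linear trend to the
    six months preceding a monitored month and flags the month when the
    observed count exceeds both the forecast upper bound and a minimum-count
    threshold; a heuristic threshold-only rule covers mostly-null histories
    where the regression is unreliable. Includes MedDRA-style term-hierarchy
    handling (PT/HLT/HLGT/SOC, SMQs, IME/DME flags), configurable counting and
    stratification of individual case safety reports, labelling of detections
    against a register of historical safety concerns with positive predictive
    value summaries, and a seeded simulator of EudraVigilance-like report
    tables with injected concern episodes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
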