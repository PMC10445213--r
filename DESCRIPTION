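Package: tmtgaze
Title: Eye-Tracking Trail Making Test Scoring and Test-Retest Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and reliability analysis for a computerized, eye-tracked
    Trail Making Test (TMT). Detects fixations, saccades and blinks from raw
    gaze samples with velocity/acceleration thresholds, computes nine per-trial
    test scores (completion time, speed-accuracy slope, fixation and saccade
    summaries, guiding/searching fixation counts, eye-hand span, scanpath
    length), estimates test-retest reliability per score and condition via the
    two-way mixed-effects intraclass correlation for average agreement
    (ICC(A,2)) with F-based confidence intervals and Bland-Altman agreement
    statistics, and runs a Monte-Carlo precision study of the attainable ICC
    confidence-interval widths at given sample sizes. A synthetic-data module
    generates layouts, subject cohorts, event streams and raw gaze traces with
    known ground truth so that the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
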