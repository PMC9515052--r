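Package: flickerreport
Title: Phase-Flickering Analysis and Computer-Aided Operative Notes from
    Surgical Phase Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of per-frame surgical phase annotations
    (e.g. from a phase-recognition network on laparoscopic cholecystectomy
    video) into a computer-aided operative note. Classifies sliding
    fixed-width frame buffers as uniform, transition or flickering, merges
    flicker/transition activity into FT groups, profiles each surgery by
    group and frame counts, calibrates aberrance cutoffs by ROC analysis
    with Youden's J, raises interquartile-range phase-duration alerts
    against a reference cohort, measures annotator concordance (frame
    accuracy with exact binomial intervals and confusion matrices), and
    renders narrative or synoptic report documents from standard text
    templates. Includes a synthetic cohort simulator for end-to-end testing
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    caret,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
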