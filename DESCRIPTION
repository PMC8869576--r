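Package: somnograph
Title: Sleep Staging and Abnormal-REM Quantification from Wrist-Worn Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Three-stage sleep staging from 30-second wrist-accelerometer
    activity epochs (G-values) and photoplethysmography-derived heart rate:
    Cole-Kripke sleep/awake detection, score-based light/deep classification,
    and per-night two-cluster k-means detection of REM from heart rate,
    followed by rule-based hypnogram cleanup. Includes cross-device G-value
    scaling, an abnormal-REM percentage index with Mann-Whitney threshold
    selection for REM sleep behavior disorder screening, epoch-level
    validation against reference hypnograms, cohort rank statistics, and a
    seeded overnight-sleep simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
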