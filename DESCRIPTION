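Package: ecgflow
Title: Single-Lead ECG Processing, PQRST Delineation, Beat Anomaly
    Detection and Cardiovascular Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Software pipeline for single-lead wearable electrocardiogram
    recordings: zero-phase Butterworth band-pass, running-median and mains
    notch filtering; amplitude clustering with automatic polarity
    correction of inverted leads; window-based P/Q/R/S/T fiducial
    delineation; Isolation Forest labelling of anomalous beats; and a
    tabular cardiovascular risk study comparing six classifier families.
    Includes seeded synthetic generators for multi-beat ECG signals with
    known ground-truth fiducials and for patient cohorts with prescribed
    marginal statistics, so every stage is verifiable without recording
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    rpart,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
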