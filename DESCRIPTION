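Package: ppgbp
Title: Hypertension Category Assessment from ECG and PPG Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess blood-pressure categories (normotension,
    prehypertension, hypertension) from simultaneously recorded ECG and
    photoplethysmogram (PPG) waveforms, using invasive arterial blood
    pressure (ABP) as the labelling reference. Includes a synthetic cohort
    generator with ground-truth beat and landmark times, zero-phase bandpass
    preprocessing with AC/DC normalization and forward-difference velocity
    (VPG) and acceleration (APG) waveforms, ECG R-peak detection and per-beat
    fiducial-point location (O, S, N, D; w-z; a-e and their projections),
    pulse arrival time and PPG morphological feature extraction, JNC7-style
    SBP labelling, and a classifier evaluation harness (logistic regression,
    AdaBoost stumps, k-nearest neighbours, bagged trees) with stratified
    70/30 splits, 10-fold cross-validation and sensitivity/specificity/F1
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    class,
    rpart,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
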