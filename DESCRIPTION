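Package: gamenirs
Title: Classification of Game Demand and Experimental Pain from fNIRS and
    Heart-Rate Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a functional near-infrared
    spectroscopy (fNIRS) and heart-rate analysis pipeline for classifying
    the demand of a computer game (Easy vs. Hard) and the presence of
    cold-pressor pain during play. Covers montage geometry and session I/O,
    a synthetic cohort generator with known ground truth, optical-density
    to haemoglobin conversion via the modified Beer-Lambert law, zero-phase
    Chebyshev band-pass filtering, accelerometer-gated motion-artifact
    detection and correction, correlation-based signal improvement (CBSI),
    windowed statistical and connectivity features (Pearson correlation and
    Morlet wavelet coherence), duration matching and SMOTE class balancing,
    deterministic ReliefF feature weighting with elbow cut-off, and nested
    participant-wise cross-validation over SVM, kNN, naive Bayes and random
    forest with binomial chance-level correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    pROC,
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
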