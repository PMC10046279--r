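Package: ecgsqc
Title: Signal-Quality Classification of Continuously Acquired ECG Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality assessment of 20-second, 250 Hz single-lead ECG segments
    recorded from patient monitors. Implements the full pipeline: synthetic
    labelled segment generation (quasi-periodic QRS trains with baseline wander,
    broadband noise, powerline interference, extreme spikes and blank runs),
    blank-run exclusion and amplitude cleaning, extraction of 43 hand-engineered
    time- and frequency-domain quality features, a warm-start random forest and a
    small two-dimensional convolutional network trained under balanced
    resampling, one-step 3-class and two-step binary-sequential cascade
    classification for heavily imbalanced data, and 3x3 / merged 2x2
    confusion-matrix evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    randomForest,
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
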