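Package: aoswave
Title: Arterial Pressure Waveform Analysis for Aortic Valve Stenosis
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting aortic valve stenosis from continuous
    non-invasive arterial blood pressure recordings.  Implements beat
    segmentation of 200 Hz pressure waveforms, per-beat hemodynamic
    feature extraction (systolic landmarks, dicrotic notch location by
    derivative analysis, pulse-contour stroke-volume surrogates, and
    cross-correlation baroreflex sensitivity), per-recording feature
    summarisation with age normalisation, and an imbalance-corrected,
    AUROC-optimised classification stage.  A calibrated synthetic
    hemodynamic cohort generator with full ground truth supports
    end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    data.table,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    rpart,
    signal,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
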