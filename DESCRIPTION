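Package: edamotion
Title: Emotion Recognition from Wearable Electrodermal Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for recognising emotions from galvanic skin response
    (GSR) logs recorded by a wrist wearable. Raw resistance traces are
    converted to electrodermal activity (EDA), downsampled to 2 Hz, median
    filtered, and decomposed into tonic and phasic components; skin
    conductance responses (peaks and offsets) are detected by slope and
    duration thresholds; fifteen statistical and event-related features are
    extracted per labelled segment; features are ranked by chi-square, ANOVA
    F and mutual information with Borda voting; and emotions are classified
    into Russell circumplex quadrants (Happy, Sad, Aggressive, Relaxed) by
    either a single four-class model or four one-vs-rest binary models, with
    a streaming mode that emits a thresholded prediction every 30 seconds.
    Includes a synthetic listening-experiment generator with
    quadrant-conditioned EDA dynamics for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    withr,
    randomForest,
    nnet,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
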