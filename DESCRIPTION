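Package: wriststep
Title: Hybrid Step Counting from Wrist-Worn Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts steps in raw wrist-worn triaxial accelerometer recordings
    using a hybrid pipeline: 10-second epochs are classified as walking or
    non-walking by a trainable classifier, the predicted label sequence is
    smoothed with a two-state hidden Markov model, and steps are then counted
    by tuned peak detection on the conditioned vector-magnitude signal of the
    predicted walking periods. Includes daily summary metrics (median daily
    step count, time-of-day nonwear imputation, one-minute peak cadence, wear
    quality control), a full validation-metric suite (MAPE, percent bias,
    Spearman correlation, Bland-Altman limits of agreement, classification
    metrics), and a synthetic gait simulator with known per-step ground truth
    for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    data.table,
    jsonlite,
    signal,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    optparse
Config/testthat/edition: 3
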