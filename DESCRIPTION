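Package: planomaly
Title: Autoencoder-Based Anomaly Detection for Radiotherapy Treatment Plans
Version: 0.1.0
Authors@R:
    person("planomaly", "developers", email = "planomaly@example.org",
           role = c("aut", "cre"))
Description: Unsupervised detection of questionable radiotherapy treatment
    plans from tabular plan parameters (segments, source-to-skin distance,
    collimator jaw positions, gantry angles, monitor units). Mixed
    categorical/continuous plan features are one-hot encoded into a binary
    plus continuous design matrix and scored by the reconstruction error of
    a symmetric fully connected autoencoder trained with a composite binary
    cross-entropy plus lambda-weighted mean-squared-error loss. Includes the
    TPR==1 threshold policy for imbalanced plan review, a full metric suite
    (ROC/AUC, accuracy, precision, F1, FPR, flagged-plan counts), four
    classical baseline detectors (LOF, HDBSCAN/GLOSH, one-class SVM, PCA
    reconstruction error) behind a common scoring interface with grid
    search, a synthetic plan generator with protocol-violation anomaly
    injection, and a command-line experiment harness (depth sweep, lambda
    sweep, baseline comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
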