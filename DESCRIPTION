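Package: wearesm
Title: Wearable Sensor and Experience-Sampling Analysis for Daily-Life
    Parkinson Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for free-living Parkinson's disease monitoring studies that
    combine body-worn inertial sensors (wrist and chest 6-DOF IMUs) with
    experience-sampling-method (ESM) questionnaires. Provides a synthetic
    cohort generator with a latent ON/OFF state trajectory, minute-level
    non-wear detection from the acceleration standard deviation, ESM beep
    scheduling with completion and sensor-coverage accounting, extraction of
    time- and frequency-domain features from 15-minute pre-questionnaire
    windows (tremor-band log energy, low-pass RMS, dominant frequency and
    energy ratio, amplitude range, normalized cross-correlation), and
    cross-validated logistic-regression detection of patient-reported OFF
    moments with ROC/AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
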