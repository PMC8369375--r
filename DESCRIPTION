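Package: pttbp
Title: Wearable Pulse Transit Time-Based Cuffless Blood Pressure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for cuffless blood pressure estimation from
    wearable pulse transit time (PTT) measurements. Simulates synchronized
    multichannel sessions (wearable ECG, seismocardiogram, multiwavelength
    photoplethysmograms, reference ECG and continuous arterial pressure) with
    known ground truth, aligns wearable and reference streams by their ECG
    R-peaks, band-pass filters each modality, ensemble-averages R-gated
    heartbeats in overlapping windows, selects high-quality beats by
    signal-to-noise ratio, detects the PPG diastolic foot (intersecting
    tangents) and the seismocardiogram aortic-valve-opening point, fits the
    per-participant linear model BP = K1/PTT + K2 for each pressure
    component, and evaluates agreement (mean absolute difference, RMSE,
    Pearson correlation, Bland-Altman limits, wearable cuffless-device
    grading) together with demographic comparisons of the calibration
    coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    nortest,
    signal,
    stats
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
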