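Package: carewatch
Title: Home-Care Monitoring Toolkit: Indoor Localization, Step Detection
    and ECG Anomaly Alerting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline toolkit for low-cost home-care monitoring pipelines.
    Implements probabilistic WiFi RSSI fingerprint localization based on
    per-access-point significance levels, accelerometer dual-threshold step
    detection with a motion timeout, single-lead ECG beat detection with
    wavelet denoising and an adaptive threshold, rule-based cardiac anomaly
    alerting (tachycardia, sinoatrial block, sinus pause, sinus arrhythmia),
    a fusion loop that gates position updates by motion state, an evaluation
    harness comparing the probabilistic locator against naive-Bayes and SVM
    baselines with Mann-Whitney tests, and seed-deterministic synthetic data
    generators for all three sensor streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
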