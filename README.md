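# carewatch

An offline toolkit for low-cost home-care monitoring pipelines: locating a
patient at room level from WiFi signal strength, counting steps from a phone
accelerometer, detecting heartbeats in a noisy single-lead ECG, and raising
rule-based cardiac alerts — plus the evaluation harness used to compare the
probabilistic locator against classifier baselines, and seed-deterministic
synthetic generators so the whole stack runs and is testable without any
recordings or hardware.

It is aimed at people building or studying telehealth monitoring systems who
want the signal-processing core of such a platform as plain, inspectable,
tested R.

## The methods

**Probabilistic WiFi fingerprint localization.** During calibration, repeated
RSSI scans are recorded at each position (fingerprint) `f_i`. Per
(fingerprint, BSSID) the readings are cleaned with 3·IQR fences
(`Q1 − 3·IQR < r < Q3 + 3·IQR`) and summarized by mean `r̄`, standard
deviation `S` and retained count `n`. A live reading `r` is standardized as

    t = (r − r̄) / (S / √n)

and converted to a two-sided significance level `α_{i,s}` under Student-t
with `n − 1` degrees of freedom (normal for `n > 30`). The fingerprint
probabilities are the normalized products over the BSSID universe:

    P_{f_i} = ∏_s α_{i,s} / Σ_i ∏_s α_{i,s}

accumulated in the log domain. BSSIDs never seen in a fingerprint are imputed
at a floor 20% farther from zero than the weakest observed reading, so a
missing access point is itself informative. A consecutive-win tracker (k
wins in a row, default 3) suppresses transient flips.

**Step detection.** The force-vector magnitude `|f| = √(x² + y² + z²)`
(gravity retained) is passed through a two-state machine: exceed the upper
threshold (10.3 m/s²), then drop below the lower one (9.1 m/s²) — one step.
A wearer with no step in the last 3 s counts as stationary, and the fusion
loop freezes the reported position while stationary.

**ECG beats and alerts.** Beat detection follows the classic four-stage
time-domain pipeline: wavelet (db4) soft-threshold denoising, a 5 Hz
zero-phase highpass, squaring plus 150 ms moving-window integration, and
adaptive-threshold decision logic with

    tr ← α·γ·peak + (1 − α)·tr

updated at each accepted peak (α = 0.1, γ = 0.5), a 200 ms refractory
period, and refinement to the raw-signal extremum. Q/S are window minima
around R; P/T window extrema with a prominence floor. Per-beat features are
the same-wave intervals since the previous beat (Pi…Ti) and the intra-beat
distances (Dpq, Dqr, Drs, Dst), all in ms. Expert rules over the feature
stream raise alerts for sinus tachycardia (mean rate of an n-beat window
strictly above 150 bpm), sinoatrial block vs sinus pause (a pause > 1.5× the
previous P-P interval, split by whether the remainder modulo the previous
interval is within a 50 ms margin), and respiratory sinus arrhythmia (a
coherent 0.15–0.4 Hz oscillation of the R-R series).

**Evaluation harness.** Repeated two-session holdout counts of correctly
classified scans, for the probabilistic locator and two baselines
(naive Bayes over 5 dBm bins, RBF SVM), compared pairwise with the
Mann-Whitney U test (midranks, normal approximation with tie and continuity
correction). A published benchmark table of such counts ships with the
package.

## Worked example

```r
library(carewatch)

# --- room-level localization on a synthetic flat ---------------------------
sim   <- simulate_rssi(rssi_environment(), scans_per_fp = 50,
                       test_per_fp = 100, seed = 1)
model <- calibrate(sim$calibration)
pred  <- vapply(sim$test_scans,
                function(s) fingerprint_probabilities(s, model)$winner,
                character(1))
mean(pred == sim$test_labels)           # 0.963 on 600 held-out scans

round(fingerprint_probabilities(sim$test_scans[[1]], model)$probabilities, 4)
#  living kitchen    hall    bath    bed1    bed2
#       1       0       0       0       0       0

# --- step counting ----------------------------------------------------------
walk <- simulate_walk(steps = 30, cadence_hz = 2, noise_sd = 0.05, seed = 1)
nrow(detect_steps(walk$trace))          # 30, matching the scripted count

# --- ECG with a dropped beat -> sinoatrial block alert ----------------------
ecg <- simulate_ecg(ecg_script(duration_s = 30, rate_bpm = 60,
                               rr_jitter = 0.02,
                               events = list(ecg_event_dropped_beat(15)),
                               seed = 1))
env    <- ecg_preprocess(ecg$signal)
beats  <- locate_waves(ecg$signal, detect_r_peaks(env, ecg$signal))
alerts <- evaluate_stream(beat_features(beats, ecg$signal$rate))
alerts[, c("type", "time_ms")]
#       type  time_ms
#   sa_block    17543

# --- comparing methods on the packaged benchmark counts ---------------------
counts <- reference_holdout_counts()
row <- function(m) as.numeric(counts[counts$method == m, -1])
mann_whitney(row("proposal"), row("svm"))
# $U 100    $p 0.00017962
```

The first block says the locator put 96.3% of held-out scans in the right
room and was certain about the first test scan; the step detector recovered
the scripted walk exactly; the dropped beat at 15 s produced a single
sinoatrial-block alert when the doubled P-P interval arrived; and the
proposal beats the SVM baseline with p ≈ 0.00018 on the packaged counts.

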