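# Shared fixture builders; everything generated in code, seed-fixed.

# Two-room calibration with hand-set readings (X strong in room a, weak in b).
toy_calibration <- function() {
  fa <- fingerprint("a", list(
    rssi_scan(c(X = -41, Y = -69)), rssi_scan(c(X = -39, Y = -71)),
    rssi_scan(c(X = -40, Y = -70))))
  fb <- fingerprint("b", list(
    rssi_scan(c(X = -79, Y = -51)), rssi_scan(c(X = -81, Y = -49)),
    rssi_scan(c(X = -80, Y = -50))))
  list(fa, fb)
}

# Minimal location estimate for tracker tests.
stub_estimate <- function(winner, ids = c("A", "B")) {
  p <- stats::setNames(rep(0, length(ids)), ids)
  p[winner] <- 1
  structure(list(probabilities = p, winner = winner),
            class = "location_estimate")
}

# End-to-end: synthetic ECG script -> alerts.
ecg_alerts <- function(script) {
  sim <- simulate_ecg(script)
  env <- ecg_preprocess(sim$signal)
  r <- detect_r_peaks(env, sim$signal)
  feats <- beat_features(locate_waves(sim$signal, r), sim$signal$rate)
  evaluate_stream(feats)
}

# Brute-force dual-threshold step count (independent of the state-machine
# implementation): scan for an upper crossing, then the next lower crossing.
naive_step_count <- function(mag, upper, lower) {
  count <- 0L
  i <- 1L
  n <- length(mag)
  while (i <= n) {
    while (i <= n && !(mag[i] > upper)) i <- i + 1L
    while (i <= n && !(mag[i] < lower)) i <- i + 1L
    if (i <= n) count <- count + 1L
    i <- i + 1L
  }
  count
}

# Matching with tolerance for R-peak scoring.
peak_recall_precision <- function(detected, truth, tol_samples) {
  rec <- mean(vapply(truth, function(x) any(abs(detected - x) <= tol_samples),
                     logical(1)))
  prec <- mean(vapply(detected, function(x) any(abs(truth - x) <= tol_samples),
                      logical(1)))
  c(recall = rec, precision = prec)
}
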