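#' Synthetic indoor RSSI environment
#'
#' A 2-D flat with access points and fingerprint positions, generating RSSI
#' by the log-distance path-loss model plus Gaussian shadowing noise.
#' Geometry only matters to the generator: the localization pipeline treats
#' fingerprints as opaque labels. The default layout emulates a small flat
#' (roughly 12 x 7 m) with three access points at the ends and middle and
#' six room positions.
#'
#' @param ap Numeric matrix (one row per access point, columns x and y, m).
#' @param fingerprints data.frame with columns `id`, `x`, `y` (m).
#' @param tx_dbm Reference received power at 1 m, dBm.
#' @param exponent Path-loss exponent.
#' @param noise_sd Shadowing noise standard deviation, dBm (>= 0).
#' @return A list of class `rssi_environment`.
#' @export
rssi_environment <- function(
    ap = cbind(x = c(0.5, 6.5, 11.5), y = c(1.0, 6.5, 2.0)),
    fingerprints = data.frame(
      id = c("living", "kitchen", "hall", "bath", "bed1", "bed2"),
      x = c(2.5, 1.5, 6.0, 8.5, 10.5, 4.0),
      y = c(5.0, 1.5, 3.0, 6.0, 1.0, 6.5),
      stringsAsFactors = FALSE),
    tx_dbm = -30, exponent = 3.0, noise_sd = 2) {
  ap <- as.matrix(ap)
  stopifnot(nrow(ap) >= 1L, ncol(ap) == 2L, nrow(fingerprints) >= 2L,
            all(c("id", "x", "y") %in% names(fingerprints)), noise_sd >= 0)
  if (anyDuplicated(fingerprints$id)) stop("fingerprint ids must be unique")
  rownames(ap) <- sprintf("ap%02d", seq_len(nrow(ap)))
  structure(list(ap = ap, fingerprints = fingerprints, tx_dbm = tx_dbm,
                 exponent = exponent, noise_sd = noise_sd),
            class = "rssi_environment")
}

.rssi_at <- function(env, x, y) {
  d <- sqrt((env$ap[, 1] - x)^2 + (env$ap[, 2] - y)^2)
  d <- pmax(d, 0.1)  # AP coincident with the position
  mu <- env$tx_dbm - 10 * env$exponent * log10(d)
  r <- mu + stats::rnorm(length(mu), 0, env$noise_sd)
  pmin(pmax(r, -100), -20)
}

#' Simulate calibration and labeled test scans
#'
#' For each fingerprint position, draws `scans_per_fp` calibration scans and
#' `test_per_fp` held-out labeled scans from the log-distance model
#' `RSSI = tx - 10 * exponent * log10(d) + N(0, noise_sd)`, truncated to
#' [-100, -20] dBm. Deterministic for a fixed seed.
#'
#' @param env An [rssi_environment()].
#' @param scans_per_fp Calibration scans per fingerprint (default 50).
#' @param test_per_fp Held-out labeled scans per fingerprint.
#' @param seed Integer seed.
#' @return List with `calibration` (list of [fingerprint()]), `test_scans`
#'   (list of [rssi_scan()]) and `test_labels` (character).
#' @export
simulate_rssi <- function(env = rssi_environment(), scans_per_fp = 50L,
                          test_per_fp = scans_per_fp, seed = 1L) {
  stopifnot(inherits(env, "rssi_environment"), scans_per_fp >= 2L)
  set.seed(seed)
  bssids <- rownames(env$ap)
  draw <- function(fp_row, k, t0) {
    lapply(seq_len(k), function(j) {
      rssi_scan(stats::setNames(.rssi_at(env, fp_row$x, fp_row$y), bssids),
                timestamp = t0 + j)
    })
  }
  calib <- lapply(seq_len(nrow(env$fingerprints)), function(i) {
    fp <- env$fingerprints[i, ]
    fingerprint(fp$id, draw(fp, scans_per_fp, 0))
  })
  test_scans <- list()
  test_labels <- character(0)
  for (i in seq_len(nrow(env$fingerprints))) {
    fp <- env$fingerprints[i, ]
    sc <- draw(fp, test_per_fp, 10000)
    test_scans <- c(test_scans, sc)
    test_labels <- c(test_labels, rep(fp$id, test_per_fp))
  }
  list(calibration = calib, test_scans = test_scans, test_labels = test_labels)
}

#' Simulate a walking accelerometer trace with ground-truth steps
#'
#' The magnitude follows `9.81 + amplitude * sin(2*pi*cadence*t)` during a
#' single walking bout (one full oscillation per step) and rests at gravity
#' before and after, with additive Gaussian noise; the pattern is placed on
#' the z axis. Ground-truth step times are the oscillation troughs, matching
#' the detector's convention of time-stamping a step at the completing
#' lower-threshold crossing.
#'
#' @param steps Number of steps in the bout.
#' @param cadence_hz Step rate, Hz (default 2).
#' @param amplitude Oscillation amplitude, m/s^2 (default 1.0).
#' @param noise_sd Additive noise sd, m/s^2.
#' @param rate_hz Sampling rate, Hz (default 50).
#' @param rest_s Rest duration before and after the bout, s.
#' @param seed Integer seed.
#' @return List with `trace` (data.frame t, x, y, z) and `truth`
#'   (numeric step times, s).
#' @export
simulate_walk <- function(steps = 20L, cadence_hz = 2, amplitude = 1.0,
                          noise_sd = 0.05, rate_hz = 50, rest_s = 2,
                          seed = 1L) {
  stopifnot(steps >= 1L, cadence_hz > 0, amplitude > 0, noise_sd >= 0,
            rate_hz > 0, rest_s >= 0)
  set.seed(seed)
  bout <- steps / cadence_hz
  total <- 2 * rest_s + bout
  t <- seq(0, total, by = 1 / rate_hz)
  mag <- rep(9.81, length(t))
  inb <- t >= rest_s & t < rest_s + bout
  mag[inb] <- 9.81 + amplitude * sin(2 * pi * cadence_hz * (t[inb] - rest_s))
  mag <- mag + stats::rnorm(length(t), 0, noise_sd)
  truth <- rest_s + (seq_len(steps) - 1 + 0.75) / cadence_hz
  list(trace = data.frame(t = t, x = 0, y = 0, z = mag), truth = truth)
}

#' Default synthetic beat morphology
#'
#' Each beat is a sum of five Gaussian bumps. Amplitudes in mV, widths
#' (Gaussian sigma) and offsets relative to R in ms.
#'
#' @return data.frame with columns `wave`, `amp`, `width_ms`, `offset_ms`.
#' @export
ecg_morphology <- function() {
  data.frame(
    wave = c("p", "q", "r", "s", "t"),
    amp = c(0.15, -0.15, 1.0, -0.15, 0.30),
    width_ms = c(25, 8, 10, 8, 45),
    offset_ms = c(-160, -30, 0, 30, 250),
    stringsAsFactors = FALSE)
}

#' Pathology events for the ECG generator
#'
#' @param start_s,end_s Episode bounds in seconds.
#' @param bpm Episode heart rate.
#' @name ecg_events
#' @return A tagged list describing the event.
#' @export
ecg_event_tachycardia <- function(start_s, end_s, bpm = 160) {
  stopifnot(end_s > start_s, bpm > 0)
  list(kind = "tachycardia", start_s = start_s, end_s = end_s, bpm = bpm)
}

#' @rdname ecg_events
#' @param at_s Time (s) after which the next beat is dropped (the following
#'   P-P and R-R intervals double exactly).
#' @export
ecg_event_dropped_beat <- function(at_s) {
  list(kind = "dropped_beat", at_s = at_s)
}

#' @rdname ecg_events
#' @param ratio Pause length as a multiple of the running interval; choose a
#'   non-integer (default 1.8) for a pause that is not a multiple.
#' @export
ecg_event_pause <- function(at_s, ratio = 1.8) {
  stopifnot(ratio > 1)
  list(kind = "pause", at_s = at_s, ratio = ratio)
}

#' @rdname ecg_events
#' @param freq_hz Respiratory modulation frequency (default 0.25 Hz).
#' @param depth Fractional R-R modulation depth (default 0.15).
#' @export
ecg_event_resp_modulation <- function(freq_hz = 0.25, depth = 0.15) {
  stopifnot(freq_hz > 0, depth > 0, depth < 1)
  list(kind = "resp_modulation", freq_hz = freq_hz, depth = depth)
}

#' Script for the synthetic ECG generator
#'
#' @param duration_s Record length, s.
#' @param rate_bpm Base heart rate, bpm.
#' @param rr_jitter Fractional R-R jitter: each interval is multiplied by
#'   `1 + u_i` where `u_i` is a three-point moving average of independent
#'   `U(-rr_jitter, +rr_jitter)` draws. The average keeps the jitter bounded
#'   by `rr_jitter` (so jitter f keeps windowed relative spread below 2f)
#'   while making consecutive cycles strongly correlated, as physiologic
#'   sinus variability is; a sinoatrial pause therefore remains a
#'   near-multiple of the neighbouring P-P cycles.
#' @param rate_hz Sampling rate, Hz (default 256).
#' @param noise_sd Additive Gaussian noise, mV.
#' @param morphology Wave table as from [ecg_morphology()].
#' @param events List of `ecg_event_*` objects.
#' @param seed Integer seed.
#' @return A list of class `ecg_script`.
#' @export
ecg_script <- function(duration_s = 10, rate_bpm = 60, rr_jitter = 0,
                       rate_hz = 256, noise_sd = 0,
                       morphology = ecg_morphology(), events = list(),
                       seed = 1L) {
  stopifnot(duration_s > 0, rate_bpm > 0, rr_jitter >= 0, rr_jitter < 1,
            rate_hz > 0, noise_sd >= 0)
  timed <- Filter(function(e) e$kind %in% c("tachycardia", "dropped_beat", "pause"),
                  events)
  if (length(timed) > 1L) {
    spans <- lapply(timed, function(e) {
      if (e$kind == "tachycardia") c(e$start_s, e$end_s) else c(e$at_s, e$at_s + 2)
    })
    spans <- spans[order(vapply(spans, `[`, numeric(1), 1))]
    for (i in seq_along(spans)[-1]) {
      if (spans[[i]][1] < spans[[i - 1]][2]) stop("overlapping pathology events")
    }
  }
  structure(list(duration_s = duration_s, rate_bpm = rate_bpm,
                 rr_jitter = rr_jitter, rate_hz = rate_hz, noise_sd = noise_sd,
                 morphology = morphology, events = events, seed = seed),
            class = "ecg_script")
}

#' Generate a synthetic ECG with ground-truth annotations
#'
#' Beats are laid down from 0.5 s until the end of the record; each R-R
#' interval follows the base rate, modified in order by any tachycardia
#' episode, respiratory modulation, jitter, and one-shot dropped-beat /
#' pause events. Each beat contributes one Gaussian bump per wave of the
#' morphology table. Beats whose waves would extend outside the record are
#' not scripted.
#'
#' @param script An [ecg_script()].
#' @return List with `signal` (an [ecg_signal()]), `truth` (data.frame of
#'   ground-truth sample indices p, q, r, s, t) and `beat_times_s`.
#' @export
simulate_ecg <- function(script = ecg_script()) {
  stopifnot(inherits(script, "ecg_script"))
  set.seed(script$seed)
  mor <- script$morphology
  rate <- script$rate_hz
  dur <- script$duration_s
  events <- script$events

  tachy <- Filter(function(e) e$kind == "tachycardia", events)
  resp <- Filter(function(e) e$kind == "resp_modulation", events)
  oneshot <- Filter(function(e) e$kind %in% c("dropped_beat", "pause"), events)
  used <- logical(length(oneshot))

  lead <- max(c(0, -mor$offset_ms)) / 1000   # room for the earliest wave
  tail <- max(c(0, mor$offset_ms)) / 1000

  # smooth bounded jitter: MA(3) of iid uniform draws (|u| <= rr_jitter)
  max_bpm <- max(script$rate_bpm,
                 vapply(tachy, `[[`, numeric(1), "bpm") + 0)
  n_max <- as.integer(ceiling(dur * max_bpm / 60)) + 8L
  u <- if (script$rr_jitter > 0) {
    v <- stats::runif(n_max + 2L, -script$rr_jitter, script$rr_jitter)
    (v[1:n_max] + v[2:(n_max + 1L)] + v[3:(n_max + 2L)]) / 3
  } else numeric(n_max)

  beat_times <- numeric(0)
  t <- max(0.5, lead + 0.05)
  b <- 0L
  while (t <= dur - tail - 0.05) {
    beat_times <- c(beat_times, t)
    b <- b + 1L
    bpm <- script$rate_bpm
    for (e in tachy) if (t >= e$start_s && t < e$end_s) bpm <- e$bpm
    rr <- 60 / bpm
    for (e in resp) rr <- rr * (1 + e$depth * sin(2 * pi * e$freq_hz * t))
    rr <- rr * (1 + u[min(b, n_max)])
    for (i in seq_along(oneshot)) {
      e <- oneshot[[i]]
      if (!used[i] && t >= e$at_s) {
        rr <- if (e$kind == "dropped_beat") 2 * rr else e$ratio * rr
        used[i] <- TRUE
      }
    }
    t <- t + rr
  }

  n <- as.integer(round(dur * rate))
  tgrid <- (seq_len(n) - 1) / rate
  x <- numeric(n)
  for (bt in beat_times) {
    for (w in seq_len(nrow(mor))) {
      if (mor$amp[w] == 0) next
      mu <- bt + mor$offset_ms[w] / 1000
      sd <- mor$width_ms[w] / 1000
      lo <- max(1L, as.integer(floor((mu - 5 * sd) * rate)))
      hi <- min(n, as.integer(ceiling((mu + 5 * sd) * rate)) + 1L)
      if (lo > hi) next
      seg <- lo:hi
      x[seg] <- x[seg] + mor$amp[w] * exp(-((tgrid[seg] - mu)^2) / (2 * sd^2))
    }
  }
  if (script$noise_sd > 0) x <- x + stats::rnorm(n, 0, script$noise_sd)

  idx <- function(off_ms) as.integer(round((beat_times + off_ms / 1000) * rate)) + 1L
  truth <- data.frame(p = if (mor$amp[mor$wave == "p"] != 0) idx(mor$offset_ms[mor$wave == "p"]) else NA_integer_,
                      q = idx(mor$offset_ms[mor$wave == "q"]),
                      r = idx(mor$offset_ms[mor$wave == "r"]),
                      s = idx(mor$offset_ms[mor$wave == "s"]),
                      t = if (mor$amp[mor$wave == "t"] != 0) idx(mor$offset_ms[mor$wave == "t"]) else NA_integer_)
  keep <- truth$r >= 1L & truth$r <= n
  truth <- truth[keep, , drop = FALSE]
  rownames(truth) <- NULL
  list(signal = ecg_signal(x, rate), truth = truth,
       beat_times_s = beat_times[keep])
}
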