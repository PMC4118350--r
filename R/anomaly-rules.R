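#' Configuration for the cardiac anomaly rules
#'
#' @param rate_bpm Tachycardia rate threshold in beats per minute
#'   (default 150, strict inequality).
#' @param window_beats Window length n (beats) over which the mean rate is
#'   evaluated and alerts of one type are deduplicated (default 5, >= 2).
#' @param pause_ratio Pause detection ratio: a P-P interval more than this
#'   multiple of its predecessor counts as a pause (default 1.5).
#' @param margin_ms Margin e (ms) deciding whether a pause is a near-multiple
#'   of the preceding P-P interval (default 50).
#' @param variability_fraction Minimum (max - min)/mean of a windowed R-R
#'   sequence for the sinus-arrhythmia rule (default 0.1).
#' @param resp_band_hz Respiratory frequency band, Hz (default 0.15-0.4).
#' @param arrhythmia_window R-R window length (beats) used by the stream
#'   evaluator for the sinus-arrhythmia rule (default 16; the rule itself
#'   accepts any window >= 8).
#' @param coherence Fraction of the variability fraction that the dominant
#'   respiratory-band oscillation's fitted amplitude must explain (default
#'   0.5): incoherent beat-to-beat jitter spreads its power across the
#'   spectrum and cannot reach this, a real respiratory modulation
#'   concentrates its full depth in one bin.
#' @param symmetric_remainder Compare the modulus from both sides
#'   (`min(rem, prev - rem)`), so pauses slightly under a multiple also
#'   count as multiples. Default TRUE.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(rate_bpm = 150, window_beats = 5L, pause_ratio = 1.5,
                        margin_ms = 50, variability_fraction = 0.1,
                        resp_band_hz = c(0.15, 0.4),
                        arrhythmia_window = 16L, coherence = 0.5,
                        symmetric_remainder = TRUE) {
  stopifnot(rate_bpm > 0, window_beats >= 2L, pause_ratio > 0, margin_ms > 0,
            variability_fraction > 0, variability_fraction < 1,
            length(resp_band_hz) == 2L, resp_band_hz[1] < resp_band_hz[2],
            arrhythmia_window >= 8L, coherence > 0, coherence <= 1)
  structure(list(rate_bpm = rate_bpm, window_beats = as.integer(window_beats),
                 pause_ratio = pause_ratio, margin_ms = margin_ms,
                 variability_fraction = variability_fraction,
                 resp_band_hz = resp_band_hz,
                 arrhythmia_window = as.integer(arrhythmia_window),
                 coherence = coherence,
                 symmetric_remainder = symmetric_remainder),
            class = "rule_config")
}

.pp_remainder <- function(p_curr, p_prev, symmetric = TRUE) {
  rem <- p_curr %% p_prev
  if (symmetric) min(rem, p_prev - rem) else rem
}

#' Sinus tachycardia rule over an R-R window
#'
#' Fires iff the mean heart rate over the n-beat window starting at `k`
#' strictly exceeds the threshold: `n * 60000 / sum(rr[k..k+n-1]) > rate_bpm`.
#'
#' @param rr Numeric vector of R-R intervals in ms (> 0).
#' @param k Start index of the window (1-based).
#' @param n Window length in beats; defaults to the config's.
#' @param config A [rule_config()].
#' @return Logical.
#' @export
tachycardia_rule <- function(rr, k = 1L, n = config$window_beats,
                             config = rule_config()) {
  if (k < 1L || k + n - 1L > length(rr)) stop("window out of range")
  w <- rr[k:(k + n - 1L)]
  if (any(w <= 0)) stop("R-R intervals must be positive")
  n * 60000 / sum(w) > config$rate_bpm
}

#' Sinoatrial block rule on a P-P interval pair
#'
#' Fires iff the current P-P interval is a long pause
#' (`p_curr / p_prev > pause_ratio`) AND is a near-multiple of the previous
#' interval (remainder below the margin e): a dropped beat with the sinus
#' clock still running.
#'
#' @param p_prev,p_curr Consecutive P-P intervals in ms (> 0).
#' @param config A [rule_config()].
#' @return Logical.
#' @export
sa_block_rule <- function(p_prev, p_curr, config = rule_config()) {
  stopifnot(p_prev > 0, p_curr > 0)
  p_curr / p_prev > config$pause_ratio &&
    .pp_remainder(p_curr, p_prev, config$symmetric_remainder) < config$margin_ms
}

#' Sinus pause rule on a P-P interval pair
#'
#' The complement of [sa_block_rule()] on the same pause: fires iff the
#' interval ratio exceeds the pause ratio AND the remainder is at least the
#' margin, i.e. the pause is not a multiple of the underlying P-P cycle.
#' By construction the two rules never both fire on one pair.
#'
#' @inheritParams sa_block_rule
#' @return Logical.
#' @export
sinus_pause_rule <- function(p_prev, p_curr, config = rule_config()) {
  stopifnot(p_prev > 0, p_curr > 0)
  p_curr / p_prev > config$pause_ratio &&
    .pp_remainder(p_curr, p_prev, config$symmetric_remainder) >= config$margin_ms
}

#' Respiratory sinus arrhythmia rule over an R-R window
#'
#' Fires iff (a) the window's relative spread -- `(max - min)` over the
#' window midrange `(max + min)/2` -- exceeds the variability fraction (the
#' midrange denominator guarantees that bounded multiplicative jitter of
#' fraction `f` can never exceed a spread of `2f`, so e.g. 5% jitter is
#' structurally below the default 0.1 fraction), (b) the variation is
#' beat-to-beat gradual (every
#' consecutive interval ratio stays within the pause ratio, excluding
#' step-like rate changes and isolated pauses, which are other pathologies),
#' and (c) the dominant oscillation of the linearly detrended window is a
#' coherent respiratory-band rhythm: the largest periodogram bin lies in
#' `resp_band_hz` (beat series treated as evenly sampled at the mean R-R
#' interval) and its fitted sinusoid amplitude `2*sqrt(P_k)/m` explains at
#' least `coherence * variability_fraction` of the mean R-R interval.
#'
#' @param rr Numeric vector of at least 8 R-R intervals in ms.
#' @param config A [rule_config()].
#' @return Logical.
#' @export
sinus_arrhythmia_rule <- function(rr, config = rule_config()) {
  m <- length(rr)
  if (m < 8L) stop("sinus-arrhythmia rule needs a window of >= 8 beats")
  if (any(rr <= 0)) stop("R-R intervals must be positive")
  spread <- (max(rr) - min(rr)) / ((max(rr) + min(rr)) / 2)
  if (spread <= config$variability_fraction) return(FALSE)
  ratios <- rr[-1] / rr[-m]
  if (any(ratios > config$pause_ratio | ratios < 1 / config$pause_ratio)) {
    return(FALSE)
  }

  res <- unname(stats::residuals(stats::lm(rr ~ seq_len(m))))
  pw <- Mod(stats::fft(res))^2
  half <- pw[2:(m %/% 2 + 1)]             # drop DC, keep up to Nyquist
  if (sum(half) <= 0) return(FALSE)
  fs <- 1000 / mean(rr)                   # beats per second
  freqs <- (1:(m %/% 2)) * fs / m
  j <- which.max(half)
  amp <- 2 * sqrt(half[j]) / m            # fitted sinusoid amplitude, ms
  freqs[j] >= config$resp_band_hz[1] && freqs[j] <= config$resp_band_hz[2] &&
    amp >= config$coherence * config$variability_fraction * mean(rr)
}

#' Evaluate all rules over a beat-feature stream
#'
#' Slides the tachycardia and sinus-arrhythmia rules over the R-R sequence
#' and the SA-block/sinus-pause pair rules over consecutive P-P intervals.
#' Alerts are edge-triggered: a rule that stays true over consecutive
#' windows yields one alert for the episode, and further alerts of the same
#' type are suppressed within the deduplication window. SA block and sinus
#' pause are mutually exclusive on a given interval pair.
#'
#' @param features A [beat_features()] data.frame (time-ordered).
#' @param config A [rule_config()].
#' @return data.frame of class `alerts` with columns `type`, `time_ms` and
#'   list-column `evidence` (the contributing intervals).
#' @export
evaluate_stream <- function(features, config = rule_config()) {
  stopifnot(is.data.frame(features))
  if (nrow(features) > 1L && is.unsorted(features$time_ms)) {
    stop("features must be time-ordered")
  }
  alerts <- list()
  add <- function(type, time_ms, evidence) {
    alerts[[length(alerts) + 1L]] <<- list(type = type, time_ms = time_ms,
                                           evidence = evidence)
  }
  nb <- nrow(features)
  rr <- features$Ri
  pp <- features$Pi
  tms <- features$time_ms

  # --- windowed R-R rules (tachycardia, sinus arrhythmia), edge-triggered
  run_windowed <- function(type, width, fire) {
    ok <- which(!is.na(rr))
    if (length(ok) < width) return(invisible())
    prev <- FALSE
    last_beat <- -Inf
    for (j in seq_len(length(ok) - width + 1L)) {
      idx <- ok[j:(j + width - 1L)]
      now <- fire(rr[idx])
      end_beat <- idx[width]
      if (now && !prev && end_beat - last_beat > max(width, config$window_beats)) {
        add(type, tms[end_beat], rr[idx])
        last_beat <- end_beat
      }
      prev <- now
    }
  }
  run_windowed("tachycardia", config$window_beats,
               function(w) tachycardia_rule(w, 1L, length(w), config))
  if (sum(!is.na(rr)) >= config$arrhythmia_window) {
    run_windowed("sinus_arrhythmia", config$arrhythmia_window,
                 function(w) sinus_arrhythmia_rule(w, config))
  }

  # --- P-P pair rules, mutually exclusive, deduplicated
  okp <- which(!is.na(pp))
  last_pair <- c(sa_block = -Inf, sinus_pause = -Inf)
  for (j in seq_along(okp)[-1]) {
    i_prev <- okp[j - 1L]
    i_curr <- okp[j]
    if (i_curr - i_prev != 1L) next   # need consecutive beats
    prev_pp <- pp[i_prev]
    curr_pp <- pp[i_curr]
    type <- if (sa_block_rule(prev_pp, curr_pp, config)) "sa_block"
            else if (sinus_pause_rule(prev_pp, curr_pp, config)) "sinus_pause"
            else NA_character_
    if (!is.na(type) && i_curr - last_pair[[type]] > config$window_beats) {
      add(type, tms[i_curr], c(prev_pp, curr_pp))
      last_pair[[type]] <- i_curr
    }
  }

  if (length(alerts) == 0L) {
    out <- data.frame(type = character(0), time_ms = numeric(0))
    out$evidence <- list()
  } else {
    out <- data.frame(
      type = vapply(alerts, `[[`, character(1), "type"),
      time_ms = vapply(alerts, `[[`, numeric(1), "time_ms"))
    out$evidence <- lapply(alerts, `[[`, "evidence")
    out <- out[order(out$time_ms), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("alerts", "data.frame")
  out
}
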