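#' Construct a single-lead ECG signal
#'
#' @param samples Numeric vector of amplitudes (mV).
#' @param rate Sampling rate in Hz (> 0).
#' @return An object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar (Hz)")
  }
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "ecg_signal")
}

#' ECG detector parameters
#'
#' Defaults are this package's choices for a 256 Hz single-lead recording:
#' db4 wavelet denoising with the removed detail bands sitting above 45 Hz,
#' a 5 Hz second-order Butterworth highpass, squaring plus a 150 ms
#' moving-window integration as the non-linear lowpass, adaptive threshold
#' constants `alpha = 0.1`, `gamma = 0.5`, a 200 ms refractory period, 60 ms
#' Q/S search half-windows, a 200 ms P window before Q and a 400 ms T window
#' after S.
#'
#' @param wavelet_levels Detail levels to denoise; `NULL` chooses the number
#'   of levels whose band lies fully above 45 Hz at the signal's rate.
#' @param highpass_hz Highpass cutoff, Hz.
#' @param integration_ms Moving-window integration length, ms.
#' @param alpha,gamma Adaptive-threshold constants in (0, 1].
#' @param refractory_ms Minimum R-R separation enforced at detection, ms.
#' @param qs_window_ms Half-window around R searched for the Q and S troughs.
#' @param p_window_ms Window before Q searched for the P peak, ms.
#' @param t_window_ms Window after S searched for the T peak, ms.
#' @param refine_ms Half-window for snapping an envelope detection to the
#'   raw-signal maximum, ms.
#' @param prominence_mv P/T candidates below this prominence (peak value
#'   minus window median) are reported absent.
#' @return A list of class `ecg_params`.
#' @export
ecg_params <- function(wavelet_levels = NULL, highpass_hz = 5,
                       integration_ms = 150, alpha = 0.1, gamma = 0.5,
                       refractory_ms = 200, qs_window_ms = 60,
                       p_window_ms = 200, t_window_ms = 400,
                       refine_ms = 50, prominence_mv = 0.05) {
  stopifnot(alpha > 0, alpha <= 1, gamma > 0, gamma <= 1,
            refractory_ms > 0, qs_window_ms > 0, p_window_ms > 0,
            t_window_ms > 0, integration_ms > 0, highpass_hz > 0)
  structure(list(wavelet_levels = wavelet_levels, highpass_hz = highpass_hz,
                 integration_ms = integration_ms, alpha = alpha, gamma = gamma,
                 refractory_ms = refractory_ms, qs_window_ms = qs_window_ms,
                 p_window_ms = p_window_ms, t_window_ms = t_window_ms,
                 refine_ms = refine_ms, prominence_mv = prominence_mv),
            class = "ecg_params")
}

.ms_to_samples <- function(ms, rate) max(1L, as.integer(round(ms / 1000 * rate)))

#' Preprocess an ECG signal into a QRS-emphasizing envelope
#'
#' Cascade of (1) wavelet soft-threshold denoising, (2) linear highpass
#' filtering (zero-phase Butterworth) to remove baseline wander, and (3) a
#' non-linear lowpass: squaring followed by moving-window integration. The
#' result is a non-negative envelope, same length as the input, whose local
#' maxima track QRS energy.
#'
#' @param signal An [ecg_signal()].
#' @param params An [ecg_params()].
#' @return Numeric envelope (arbitrary units, >= 0).
#' @export
ecg_preprocess <- function(signal, params = ecg_params()) {
  stopifnot(inherits(signal, "ecg_signal"))
  x <- signal$samples
  rate <- signal$rate
  w <- .ms_to_samples(params$integration_ms, rate)
  if (length(x) < w) stop("signal shorter than one integration window")

  levels <- params$wavelet_levels
  if (is.null(levels)) {
    # keep thresholding to detail bands whose lower edge is >= 45 Hz
    levels <- 0L
    while (rate / 2^(levels + 2) >= 45) levels <- levels + 1L
    levels <- max(1L, levels)
  }
  den <- denoise_dwt(x - mean(x), levels = levels)  # demean: exact DC removal

  bf <- signal::butter(2, params$highpass_hz / (rate / 2), type = "high")
  hp <- as.numeric(signal::filtfilt(bf, den))

  sq <- hp^2
  env <- stats::filter(sq, rep(1 / w, w), sides = 2)
  env <- as.numeric(env)
  env[is.na(env)] <- 0
  env
}

#' Adaptive threshold update
#'
#' `tr <- alpha * gamma * peak + (1 - alpha) * tr`: an exponential tracker of
#' a fixed fraction `gamma` of the recent accepted peak height, with memory
#' `1 - alpha`.
#'
#' @param tr Current threshold (envelope units, >= 0).
#' @param peak Newly accepted peak height (envelope units, >= 0).
#' @param alpha,gamma Constants in (0, 1].
#' @return The updated threshold.
#' @export
update_threshold <- function(tr, peak, alpha, gamma) {
  alpha * gamma * peak + (1 - alpha) * tr
}

#' Detect R peaks from a preprocessed envelope
#'
#' Scans the local maxima of the envelope, accepting those exceeding the
#' running adaptive threshold and separated from the previous acceptance by
#' at least the refractory period; the threshold is updated via
#' [update_threshold()] at each acceptance. Each accepted detection is then
#' refined to the raw-signal maximum within `refine_ms`. The threshold is
#' initialized at `gamma` times the envelope maximum over the first two
#' seconds, so detection is invariant under positive rescaling of the input.
#'
#' @param env Envelope from [ecg_preprocess()].
#' @param signal The original [ecg_signal()] (for refinement and the rate).
#' @param params An [ecg_params()].
#' @return Integer vector of R sample indices (possibly empty), increasing.
#' @export
detect_r_peaks <- function(env, signal, params = ecg_params()) {
  stopifnot(inherits(signal, "ecg_signal"), length(env) == length(signal$samples))
  rate <- signal$rate
  n <- length(env)
  refr <- .ms_to_samples(params$refractory_ms, rate)
  refine <- .ms_to_samples(params$refine_ms, rate)

  init_span <- seq_len(min(n, as.integer(2 * rate)))
  tr <- params$gamma * max(env[init_span])
  if (max(env) <= 0) return(integer(0))

  is_max <- c(FALSE, env[2:(n - 1)] > env[1:(n - 2)] &
                env[2:(n - 1)] >= env[3:n], FALSE)
  cand <- which(is_max)
  accepted <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (env[i] > tr && i - last >= refr) {
      accepted <- c(accepted, i)
      last <- i
      tr <- update_threshold(tr, env[i], params$alpha, params$gamma)
    }
  }
  if (length(accepted) == 0L) return(integer(0))

  raw <- signal$samples
  refined <- vapply(accepted, function(i) {
    lo <- max(1L, i - refine)
    hi <- min(n, i + refine)
    lo + which.max(raw[lo:hi]) - 1L
  }, integer(1))
  sort(unique(refined))
}

#' Locate P, Q, S and T around detected R peaks
#'
#' Q is the minimum of the raw signal in the window before R, S the minimum
#' in the window after R; P is the maximum in the P window before Q and T
#' the maximum in the T window after S. P and T are reported absent (NA)
#' when the candidate's prominence over the window median falls below the
#' configured floor. Beats whose Q/S windows would extend past the record
#' are dropped; P/T windows are truncated at the record edges.
#'
#' @param signal An [ecg_signal()].
#' @param r_indices Sorted integer R sample indices.
#' @param params An [ecg_params()].
#' @return data.frame with integer columns `p`, `q`, `r`, `s`, `t` (one row
#'   per retained beat; `p`/`t` may be NA), satisfying p < q < r < s < t
#'   where present.
#' @export
locate_waves <- function(signal, r_indices, params = ecg_params()) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (is.unsorted(r_indices, strictly = TRUE)) stop("r_indices must be sorted")
  raw <- signal$samples
  rate <- signal$rate
  n <- length(raw)
  qs <- .ms_to_samples(params$qs_window_ms, rate)
  pw <- .ms_to_samples(params$p_window_ms, rate)
  tw <- .ms_to_samples(params$t_window_ms, rate)

  rows <- lapply(as.integer(r_indices), function(r) {
    if (r - qs < 1L || r + qs > n) return(NULL)  # truncated QRS window
    q <- (r - qs) + which.min(raw[(r - qs):(r - 1L)]) - 1L
    s <- r + which.min(raw[(r + 1L):(r + qs)])
    p <- NA_integer_
    plo <- max(1L, q - pw)
    if (plo <= q - 1L) {
      win <- raw[plo:(q - 1L)]
      cand <- plo + which.max(win) - 1L
      if (raw[cand] - stats::median(win) >= params$prominence_mv) p <- cand
    }
    t <- NA_integer_
    thi <- min(n, s + tw)
    if (s + 1L <= thi) {
      win <- raw[(s + 1L):thi]
      cand <- s + which.max(win)
      if (raw[cand] - stats::median(win) >= params$prominence_mv) t <- cand
    }
    data.frame(p = p, q = q, r = r, s = s, t = t)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(p = integer(0), q = integer(0), r = integer(0),
                      s = integer(0), t = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-beat interval features
#'
#' Converts beat annotations into the monitoring feature vector: for each
#' wave (P, Q, R, S, T) the interval in milliseconds since the same wave in
#' the previous beat (`Pi` .. `Ti`; NA for the first beat or when either
#' endpoint is absent), and the intra-beat distances `Dpq`, `Dqr`, `Drs`,
#' `Dst` in milliseconds. A `time_ms` column (time of R) is included for
#' downstream alert timing.
#'
#' @param annotations data.frame from [locate_waves()].
#' @param rate Sampling rate in Hz.
#' @return data.frame of class `beat_features` with columns `time_ms`,
#'   `Pi`, `Qi`, `Ri`, `Si`, `Ti`, `Dpq`, `Dqr`, `Drs`, `Dst`.
#' @export
beat_features <- function(annotations, rate) {
  stopifnot(is.data.frame(annotations), rate > 0)
  ms <- 1000 / rate
  n <- nrow(annotations)
  lagdiff <- function(col) {
    v <- annotations[[col]]
    if (n == 0L) return(numeric(0))
    c(NA_real_, diff(v)) * ms
  }
  out <- data.frame(
    time_ms = annotations$r * ms,
    Pi = lagdiff("p"), Qi = lagdiff("q"), Ri = lagdiff("r"),
    Si = lagdiff("s"), Ti = lagdiff("t"),
    Dpq = (annotations$q - annotations$p) * ms,
    Dqr = (annotations$r - annotations$q) * ms,
    Drs = (annotations$s - annotations$r) * ms,
    Dst = (annotations$t - annotations$s) * ms
  )
  class(out) <- c("beat_features", "data.frame")
  out
}
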