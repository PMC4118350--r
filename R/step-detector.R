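#' Step-detector configuration
#'
#' Dual thresholds on the acceleration force-vector magnitude: a step is
#' counted when the magnitude first exceeds `upper` and subsequently drops
#' below `lower`. Defaults match the deployed sensitivity (10.3 and
#' 9.1 m/s^2 around gravity at 9.81 m/s^2). `timeout_s` is the window after
#' the last step during which the wearer still counts as moving.
#'
#' @param upper Upper threshold, m/s^2.
#' @param lower Lower threshold, m/s^2; must satisfy `upper > lower > 0`.
#' @param timeout_s Motion timeout in seconds (default 3).
#' @param smooth Apply a centered moving average to the magnitude before
#'   thresholding (off by default; raw thresholding is the reference
#'   behaviour).
#' @param smooth_window Moving-average width in samples when `smooth = TRUE`.
#' @return A list of class `step_config`.
#' @export
step_config <- function(upper = 10.3, lower = 9.1, timeout_s = 3,
                        smooth = FALSE, smooth_window = 5L) {
  if (!(upper > lower && lower > 0)) stop("need upper > lower > 0")
  if (timeout_s <= 0) stop("timeout_s must be > 0")
  structure(list(upper = upper, lower = lower, timeout_s = timeout_s,
                 smooth = smooth, smooth_window = as.integer(smooth_window)),
            class = "step_config")
}

#' Euclidean force-vector magnitude
#'
#' `sqrt(x^2 + y^2 + z^2)` of the tri-axial acceleration with gravity
#' retained, so the resting magnitude sits near 9.81 m/s^2 regardless of
#' device orientation.
#'
#' @param x,y,z Acceleration components in m/s^2 (vectorized).
#' @return Non-negative magnitude in m/s^2.
#' @export
force_magnitude <- function(x, y, z) {
  if (!all(is.finite(x), is.finite(y), is.finite(z))) {
    stop("acceleration components must be finite")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Detect steps by dual-threshold crossing
#'
#' Runs a two-state machine over the magnitude series: the detector arms at
#' the first sample strictly above the upper threshold and emits one step at
#' the first subsequent sample strictly below the lower threshold (which also
#' re-disarms it). Samples exactly at a threshold never trigger.
#'
#' @param trace data.frame with columns `t` (seconds, strictly increasing)
#'   and `x`, `y`, `z` (m/s^2).
#' @param config A [step_config()].
#' @return data.frame with one column `t`: the time of the completing
#'   (lower-threshold) crossing of each step, strictly increasing.
#' @export
detect_steps <- function(trace, config = step_config()) {
  stopifnot(is.data.frame(trace), all(c("t", "x", "y", "z") %in% names(trace)))
  if (nrow(trace) == 0L) return(data.frame(t = numeric(0)))
  if (any(diff(trace$t) <= 0)) stop("trace timestamps must be strictly increasing")
  mag <- force_magnitude(trace$x, trace$y, trace$z)
  if (isTRUE(config$smooth)) {
    w <- config$smooth_window
    sm <- stats::filter(mag, rep(1 / w, w), sides = 2)
    mag <- ifelse(is.na(sm), mag, as.numeric(sm))
  }
  armed <- FALSE
  at <- numeric(0)
  for (i in seq_along(mag)) {
    if (!armed && mag[i] > config$upper) {
      armed <- TRUE
    } else if (armed && mag[i] < config$lower) {
      at <- c(at, trace$t[i])
      armed <- FALSE
    }
  }
  data.frame(t = at)
}

#' Moving/stationary state at a query time
#'
#' The wearer counts as moving iff a step fell inside the half-open window
#' `(t - timeout, t]`.
#'
#' @param steps data.frame from [detect_steps()] (or numeric step times).
#' @param t Query time, seconds.
#' @param config A [step_config()]; supplies the timeout.
#' @return `"moving"` or `"stationary"`.
#' @export
motion_state <- function(steps, t, config = step_config()) {
  times <- if (is.data.frame(steps)) steps$t else as.numeric(steps)
  if (is.unsorted(times, strictly = FALSE)) stop("steps must be time-ordered")
  if (any(times > t - config$timeout_s & times <= t)) "moving" else "stationary"
}
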