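#' Construct a single WiFi scan
#'
#' A scan is one pass over the visible access points: a named vector of RSSI
#' levels (dBm, negative; closer to 0 means stronger) keyed by BSSID.
#'
#' @param readings Named numeric vector of RSSI levels in dBm; names are
#'   BSSIDs and must be unique.
#' @param timestamp Optional scan time in seconds.
#' @return An object of class `rssi_scan`.
#' @export
rssi_scan <- function(readings, timestamp = NA_real_) {
  if (length(readings) == 0L) stop("scan must contain at least one reading")
  if (is.null(names(readings)) || any(!nzchar(names(readings)))) {
    stop("readings must be named by BSSID")
  }
  if (anyDuplicated(names(readings))) stop("duplicate BSSID in scan")
  if (!all(is.finite(readings))) stop("all RSSI readings must be finite")
  structure(list(timestamp = timestamp, readings = readings),
            class = "rssi_scan")
}

#' Construct a calibration fingerprint
#'
#' A fingerprint is a named calibration position (typically a room) together
#' with the repeated scans recorded there.
#'
#' @param id Character label of the position.
#' @param scans List of [rssi_scan()] objects; at least two are required so a
#'   standard deviation exists.
#' @return An object of class `rssi_fingerprint`.
#' @export
fingerprint <- function(id, scans) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(scans) < 2L) stop("fingerprint '", id, "' needs at least 2 scans")
  ok <- vapply(scans, inherits, logical(1), what = "rssi_scan")
  if (!all(ok)) stop("scans must all be rssi_scan objects")
  structure(list(id = id, scans = scans), class = "rssi_fingerprint")
}

#' Remove RSSI outliers with 3*IQR fences
#'
#' Retains the values strictly inside `(Q1 - 3*IQR, Q3 + 3*IQR)`. Quartiles
#' use linear interpolation between order statistics by default
#' (`stats::quantile` type 7); the method is configurable. If the fences
#' empty the set (e.g. all values identical, so both fences collapse onto the
#' data), the values equal to the median are retained instead.
#'
#' @param values Numeric vector of RSSI levels (dBm).
#' @param quartile_type Quantile algorithm passed to [stats::quantile()].
#' @return The retained values, original order preserved.
#' @export
filter_outliers <- function(values, quartile_type = 7) {
  if (length(values) == 0L) stop("values must be non-empty")
  if (!all(is.finite(values))) stop("values must be finite")
  q <- stats::quantile(values, c(0.25, 0.75), type = quartile_type, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values > q[1] - 3 * iqr & values < q[2] + 3 * iqr
  if (!any(keep)) {
    keep <- values == stats::median(values)
    if (!any(keep)) keep <- rep(TRUE, length(values))  # even-n median fallback
  }
  values[keep]
}

#' Calibrate a fingerprint model from repeated scans
#'
#' For every (fingerprint, BSSID) pair the RSSI readings are outlier-filtered
#' ([filter_outliers()]) and summarised by mean, standard deviation and
#' retained count. BSSIDs never observed in a fingerprint are imputed at the
#' global floor: 20% farther from zero than the most negative observed RSSI
#' (e.g. -90 dBm observed minimum gives a -108 dBm floor), with `sd = sd_floor`
#' and a small pseudo-count, so missing access points are distinguishable from
#' weakly received ones.
#'
#' @param fingerprints List of [fingerprint()] objects with unique ids.
#' @param sd_floor Minimum standard deviation in dBm (guards zero-variance
#'   BSSIDs); must be > 0.
#' @param imputed_n Pseudo-count assigned to imputed (never observed) entries.
#' @param quartile_type Quartile method for outlier filtering.
#' @param residual_scale Either `"standard_error"` (residuals divided by
#'   `sd/sqrt(n)`, the literal calibration-side formula) or
#'   `"standard_deviation"` (divided by `sd` alone). Echoed into the model and
#'   used as the default at location time.
#' @return An object of class `rssi_calibration` with elements `stats`
#'   (data.frame: fingerprint, bssid, mean, sd, n, imputed), `fingerprints`,
#'   `bssids`, `floor` and `config`.
#' @export
calibrate <- function(fingerprints, sd_floor = 0.5, imputed_n = 2L,
                      quartile_type = 7,
                      residual_scale = c("standard_error", "standard_deviation")) {
  residual_scale <- match.arg(residual_scale)
  if (length(fingerprints) == 0L) stop("no fingerprints supplied")
  ok <- vapply(fingerprints, inherits, logical(1), what = "rssi_fingerprint")
  if (!all(ok)) stop("fingerprints must be rssi_fingerprint objects")
  if (sd_floor <= 0) stop("sd_floor must be > 0")
  ids <- vapply(fingerprints, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("fingerprint ids must be unique")
  nscans <- vapply(fingerprints, function(f) length(f$scans), integer(1))
  if (any(nscans < 2L)) {
    stop("fingerprint '", ids[which(nscans < 2L)[1]], "' has fewer than 2 scans")
  }

  all_readings <- unlist(lapply(fingerprints, function(f) {
    lapply(f$scans, `[[`, "readings")
  }))
  bssids <- sort(unique(names(all_readings)))
  if (length(bssids) == 0L) stop("no BSSIDs observed across the calibration set")
  floor_dbm <- min(all_readings) * 1.2

  rows <- list()
  for (f in fingerprints) {
    obs <- lapply(f$scans, `[[`, "readings")
    for (b in bssids) {
      vals <- unlist(lapply(obs, function(r) unname(r[b])))
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          fingerprint = f$id, bssid = b, mean = floor_dbm, sd = sd_floor,
          n = as.integer(imputed_n), imputed = TRUE,
          stringsAsFactors = FALSE)
      } else {
        kept <- filter_outliers(vals, quartile_type = quartile_type)
        s <- if (length(kept) > 1L) stats::sd(kept) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          fingerprint = f$id, bssid = b, mean = mean(kept),
          sd = max(s, sd_floor), n = length(kept), imputed = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    stats = do.call(rbind, rows),
    fingerprints = ids,
    bssids = bssids,
    floor = floor_dbm,
    config = list(sd_floor = sd_floor, imputed_n = as.integer(imputed_n),
                  quartile_type = quartile_type,
                  residual_scale = residual_scale)
  ), class = "rssi_calibration")
}

#' Standardize a live RSSI reading against a calibrated BSSID
#'
#' Returns `(r - mean) / (sd / sqrt(n))`: the observation is scored on the
#' same scale used to standardize the calibration readings, i.e. against the
#' standard error of the fingerprint mean. Set `scale = "standard_deviation"`
#' to score against the spread of individual readings instead.
#'
#' @param r Observed RSSI (dBm).
#' @param mean,sd,n Calibrated mean (dBm), standard deviation (dBm, > 0) and
#'   retained count for the (fingerprint, BSSID) pair.
#' @param scale Divisor convention, see above.
#' @return The t-statistic (dimensionless). Vectorized over all arguments.
#' @export
standardize_residual <- function(r, mean, sd, n,
                                 scale = c("standard_error", "standard_deviation")) {
  scale <- match.arg(scale)
  if (any(sd <= 0)) stop("sd must be > 0 (apply the sd floor first)")
  if (any(n < 1)) stop("n must be >= 1")
  denom <- if (scale == "standard_error") sd / sqrt(n) else sd
  (r - mean) / denom
}

#' Two-sided significance level of a standardized residual
#'
#' Tail probability of `|t|` under a Student-t distribution with `n - 1`
#' degrees of freedom; for `n > 30` the normal distribution is used. The
#' result is clamped below at `eps` so that products of many levels never
#' collapse to exactly zero.
#'
#' @param t Standardized residual(s).
#' @param n Retained calibration count(s), >= 2.
#' @param eps Lower clamp, default 1e-300.
#' @return Significance level(s) in `(0, 1]`. Vectorized.
#' @export
alpha_level <- function(t, n, eps = 1e-300) {
  if (any(n < 2)) stop("n must be >= 2 for a significance level")
  p <- ifelse(n > 30, 2 * stats::pnorm(-abs(t)), 2 * stats::pt(-abs(t), df = n - 1))
  pmax(p, eps)
}

#' Per-fingerprint membership probabilities for a scan
#'
#' Every fingerprint is scored by the product over the model's full BSSID
#' universe of the per-BSSID significance levels; scan readings absent from
#' the scan are imputed at the model floor so all fingerprints multiply over
#' the same number of factors. Products are accumulated in the log domain and
#' normalized so probabilities sum to one. The winner is the fingerprint with
#' maximal probability; exact ties break lexicographically by id.
#'
#' @param scan An [rssi_scan()] sharing at least one BSSID with the model.
#' @param model An [calibrate()]d `rssi_calibration`.
#' @param residual_scale Overrides the model's residual scaling convention.
#' @param keep_alphas If `TRUE`, attach the fingerprint-by-BSSID matrix of
#'   significance levels as element `alphas` (diagnostics).
#' @return An object of class `location_estimate`: list with `probabilities`
#'   (named, sums to 1), `winner`, and optionally `alphas`.
#' @export
fingerprint_probabilities <- function(scan, model,
                                      residual_scale = NULL,
                                      keep_alphas = FALSE) {
  stopifnot(inherits(scan, "rssi_scan"), inherits(model, "rssi_calibration"))
  if (is.null(residual_scale)) residual_scale <- model$config$residual_scale
  if (!any(names(scan$readings) %in% model$bssids)) {
    stop("scan shares no BSSID with the calibration model")
  }
  observed <- stats::setNames(rep(model$floor, length(model$bssids)), model$bssids)
  shared <- intersect(names(scan$readings), model$bssids)
  observed[shared] <- scan$readings[shared]

  st <- model$stats
  fids <- model$fingerprints
  logp <- numeric(length(fids))
  alphas <- if (keep_alphas) {
    matrix(NA_real_, length(fids), length(model$bssids),
           dimnames = list(fids, model$bssids))
  }
  for (i in seq_along(fids)) {
    rows <- st[st$fingerprint == fids[i], , drop = FALSE]
    rows <- rows[match(model$bssids, rows$bssid), , drop = FALSE]
    tt <- standardize_residual(observed, rows$mean, rows$sd, rows$n,
                               scale = residual_scale)
    a <- alpha_level(tt, pmax(rows$n, 2L))
    if (keep_alphas) alphas[i, ] <- a
    logp[i] <- sum(log(a))
  }
  m <- max(logp)
  w <- exp(logp - m)
  probs <- stats::setNames(w / sum(w), fids)
  top <- probs[probs == max(probs)]
  winner <- sort(names(top))[1]
  out <- list(probabilities = probs, winner = winner)
  if (keep_alphas) out$alphas <- alphas
  structure(out, class = "location_estimate")
}

#' Initial state for consecutive-win location tracking
#'
#' The committed position only changes after the same fingerprint has won `k`
#' consecutive estimates, which suppresses transient flips driven by RSSI
#' fluctuation.
#'
#' @param k Required number of consecutive wins (default 3).
#' @return An object of class `track_state`.
#' @export
track_state <- function(k = 3L) {
  stopifnot(k >= 1)
  structure(list(committed = NA_character_, candidate = NA_character_,
                 count = 0L, k = as.integer(k)),
            class = "track_state")
}

#' Advance the consecutive-win tracker with a new estimate
#'
#' @param estimate A `location_estimate` (must have a winner).
#' @param state A [track_state()].
#' @return The updated `track_state`; `committed` changes only when the
#'   candidate's consecutive-win counter reaches `k`.
#' @export
update_track <- function(estimate, state) {
  stopifnot(inherits(estimate, "location_estimate"), inherits(state, "track_state"))
  w <- estimate$winner
  if (identical(w, state$candidate)) {
    state$count <- min(state$count + 1L, state$k)
  } else {
    state$candidate <- w
    state$count <- 1L
  }
  if (state$count >= state$k) state$committed <- state$candidate
  state
}

#' Locate a device: probabilities plus tracker update
#'
#' Composition of [fingerprint_probabilities()] and [update_track()].
#'
#' @inheritParams fingerprint_probabilities
#' @param state A [track_state()].
#' @return List with elements `estimate` and `state`.
#' @export
locate <- function(scan, model, state, residual_scale = NULL) {
  est <- fingerprint_probabilities(scan, model, residual_scale = residual_scale)
  list(estimate = est, state = update_track(est, state))
}
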