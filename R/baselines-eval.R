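.scan_feature_matrix <- function(scans, bssids, floor_dbm) {
  m <- matrix(floor_dbm, nrow = length(scans), ncol = length(bssids),
              dimnames = list(NULL, bssids))
  for (i in seq_along(scans)) {
    r <- scans[[i]]$readings
    shared <- intersect(names(r), bssids)
    m[i, shared] <- r[shared]
  }
  m
}

.calibration_xy <- function(fingerprints) {
  labels <- character(0)
  scans <- list()
  for (f in fingerprints) {
    scans <- c(scans, f$scans)
    labels <- c(labels, rep(f$id, length(f$scans)))
  }
  all_readings <- unlist(lapply(scans, `[[`, "readings"))
  list(scans = scans, labels = labels,
       bssids = sort(unique(names(all_readings))),
       floor = min(all_readings) * 1.2)
}

#' Train a baseline room classifier on calibration scans
#'
#' Reference classifiers for benchmarking the probabilistic locator:
#' `"bayes"` is a naive Bayes over RSSI discretized into fixed-width bins
#' (default 5 dBm, Laplace-smoothed); `"svm"` is a multiclass RBF SVM on
#' standardized features. In both cases BSSIDs missing from a scan are
#' imputed at the calibration floor (minimum observed RSSI times 1.2).
#'
#' @param method `"bayes"` or `"svm"`.
#' @param fingerprints List of [fingerprint()] objects (>= 2 positions).
#' @param bin_width Discretization bin width in dBm (naive Bayes only).
#' @param ... Passed to [e1071::svm()] (SVM only).
#' @return A classifier handle of class `rssi_baseline` usable with
#'   [predict()][predict.rssi_baseline].
#' @export
train_baseline <- function(method = c("bayes", "svm"), fingerprints,
                           bin_width = 5, ...) {
  method <- match.arg(method)
  if (length(fingerprints) < 2L) stop("need at least 2 fingerprints")
  xy <- .calibration_xy(fingerprints)
  if (length(unique(xy$labels)) < 2L) stop("single-class calibration set")
  x <- .scan_feature_matrix(xy$scans, xy$bssids, xy$floor)
  y <- factor(xy$labels)

  if (method == "bayes") {
    lo <- floor(min(x, xy$floor) / bin_width) * bin_width - bin_width
    breaks <- seq(lo, 0 + bin_width, by = bin_width)
    xf <- as.data.frame(lapply(as.data.frame(x), cut, breaks = breaks))
    fit <- e1071::naiveBayes(xf, y, laplace = 1)
    handle <- list(method = method, fit = fit, bssids = xy$bssids,
                   floor = xy$floor, breaks = breaks)
  } else {
    keep <- apply(x, 2, function(col) stats::sd(col) > 0)
    if (!any(keep)) stop("no informative BSSID columns for the SVM")
    fit <- e1071::svm(x[, keep, drop = FALSE], y, kernel = "radial",
                      scale = TRUE, ...)
    handle <- list(method = method, fit = fit, bssids = xy$bssids,
                   floor = xy$floor, keep = keep)
  }
  structure(handle, class = "rssi_baseline")
}

#' Predict fingerprints for scans with a baseline classifier
#'
#' @param object An `rssi_baseline` from [train_baseline()].
#' @param scans List of [rssi_scan()] objects (a single scan is accepted).
#' @param ... Unused.
#' @return Character vector of predicted fingerprint ids.
#' @export
predict.rssi_baseline <- function(object, scans, ...) {
  if (inherits(scans, "rssi_scan")) scans <- list(scans)
  x <- .scan_feature_matrix(scans, object$bssids, object$floor)
  if (object$method == "bayes") {
    rng <- range(object$breaks)
    x <- pmin(pmax(x, rng[1] + 1e-9), rng[2] - 1e-9)
    xf <- as.data.frame(lapply(as.data.frame(x), cut, breaks = object$breaks))
    as.character(stats::predict(object$fit, xf))
  } else {
    as.character(stats::predict(object$fit,
                                x[, object$keep, drop = FALSE]))
  }
}

#' Count correct classifications on a labeled hold-out set
#'
#' Accepts either a calibrated probabilistic model (`rssi_calibration`,
#' scored by the maximum-probability fingerprint with no time-series
#' stabilization) or a baseline classifier handle.
#'
#' @param classifier An `rssi_calibration` or `rssi_baseline`.
#' @param scans List of labeled test [rssi_scan()]s.
#' @param labels True fingerprint ids, same length as `scans`.
#' @return Integer count of correct predictions.
#' @export
evaluate_holdout <- function(classifier, scans, labels) {
  stopifnot(length(scans) == length(labels))
  universe <- if (inherits(classifier, "rssi_calibration")) {
    classifier$fingerprints
  } else if (inherits(classifier, "rssi_baseline")) {
    classifier$fit$levels
  } else stop("unsupported classifier")
  if (!all(labels %in% universe)) stop("labels outside the model's fingerprints")
  pred <- if (inherits(classifier, "rssi_calibration")) {
    vapply(scans, function(s) fingerprint_probabilities(s, classifier)$winner,
           character(1))
  } else {
    predict(classifier, scans)
  }
  sum(pred == labels)
}

#' Mann-Whitney U test (normal approximation)
#'
#' Rank-sum U with midranks for ties and a two-sided p-value from the
#' normal approximation with tie and continuity correction (the convention
#' used to compare repeated-holdout correct-classification counts). An
#' exact-permutation p-value is available for small untied samples.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact Use the exact distribution instead (requires no ties).
#' @return List with elements `U` and `p`.
#' @export
mann_whitney <- function(x, y, exact = FALSE) {
  stopifnot(length(x) > 0, length(y) > 0)
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Packaged repeated-holdout benchmark counts
#'
#' Published per-run correct-classification counts for three room-level
#' localization methods (the probabilistic fingerprint proposal, a naive
#' Bayes and an SVM), five repetitions with two directions each (train on
#' one session, classify the other). Used to exercise the comparison
#' harness without any recordings.
#'
#' @return data.frame with columns `method`, `a1`..`b5`.
#' @export
reference_holdout_counts <- function() {
  path <- system.file("extdata", "localization_holdout_counts.csv",
                      package = "carewatch", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Repeated-holdout benchmark on a synthetic environment
#'
#' For each repetition two independent sessions (calibration-sized scan
#' sets) are simulated; each method is trained on one session and scored on
#' the other, in both directions, mirroring a repeated two-session holdout.
#' The probabilistic locator is evaluated without the consecutive-win
#' stabilizer.
#'
#' @param env An [rssi_environment()].
#' @param reps Number of repetitions (default 5).
#' @param scans_per_fp Scans per fingerprint and session (default 50).
#' @param seed Integer seed.
#' @return List with `counts` (data.frame: method, a1..b<reps>, average)
#'   and `p_matrix` (pairwise Mann-Whitney p-values).
#' @export
benchmark_localization <- function(env = rssi_environment(), reps = 5L,
                                   scans_per_fp = 50L, seed = 1L) {
  methods <- c("proposal", "bayes", "svm")
  counts <- matrix(NA_integer_, nrow = 3, ncol = 2 * reps,
                   dimnames = list(methods, as.vector(
                     rbind(paste0("a", seq_len(reps)), paste0("b", seq_len(reps))))))
  for (r in seq_len(reps)) {
    sa <- simulate_rssi(env, scans_per_fp, test_per_fp = 0L,
                        seed = seed + 1000L * r)
    sb <- simulate_rssi(env, scans_per_fp, test_per_fp = 0L,
                        seed = seed + 1000L * r + 500L)
    flatten <- function(sim) {
      scans <- list(); labels <- character(0)
      for (f in sim$calibration) {
        scans <- c(scans, f$scans)
        labels <- c(labels, rep(f$id, length(f$scans)))
      }
      list(scans = scans, labels = labels)
    }
    fa <- flatten(sa); fb <- flatten(sb)
    for (m in methods) {
      clf_a <- switch(m, proposal = calibrate(sa$calibration),
                      train_baseline(m, sa$calibration))
      clf_b <- switch(m, proposal = calibrate(sb$calibration),
                      train_baseline(m, sb$calibration))
      # a_r: session-A scans classified with the model built on session B
      counts[m, paste0("a", r)] <- evaluate_holdout(clf_b, fa$scans, fa$labels)
      counts[m, paste0("b", r)] <- evaluate_holdout(clf_a, fb$scans, fb$labels)
    }
  }
  df <- data.frame(method = methods, counts, check.names = FALSE)
  df$average <- rowMeans(counts)
  pm <- matrix(1, 3, 3, dimnames = list(methods, methods))
  for (i in 1:2) for (j in (i + 1):3) {
    p <- mann_whitney(counts[i, ], counts[j, ])$p
    pm[i, j] <- p
    pm[j, i] <- p
  }
  list(counts = df, p_matrix = pm)
}
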