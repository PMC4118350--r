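#' Read a long-form scan stream CSV
#'
#' Expects columns `timestamp,bssid,rssi`; rows sharing a timestamp form one
#' scan. Errors name the offending row.
#'
#' @param path CSV file path.
#' @return List of [rssi_scan()] objects ordered by timestamp.
#' @export
read_scan_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("timestamp", "bssid", "rssi") %in% names(df))) {
    stop("scan stream needs columns timestamp,bssid,rssi")
  }
  rssi <- suppressWarnings(as.numeric(df$rssi))
  bad <- which(!is.finite(rssi))
  if (length(bad) > 0L) {
    stop("non-numeric or non-finite rssi at row ", bad[1], " of ", path)
  }
  df$rssi <- rssi
  df$timestamp <- suppressWarnings(as.numeric(df$timestamp))
  if (any(!is.finite(df$timestamp))) stop("non-numeric timestamp in ", path)
  out <- lapply(split(df, df$timestamp), function(g) {
    if (anyDuplicated(g$bssid)) {
      stop("duplicate BSSID within scan at timestamp ", g$timestamp[1])
    }
    rssi_scan(stats::setNames(g$rssi, g$bssid), timestamp = g$timestamp[1])
  })
  out[order(vapply(out, `[[`, numeric(1), "timestamp"))]
}

#' Write a scan stream to long-form CSV
#'
#' @param scans List of [rssi_scan()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_stream <- function(scans, path) {
  rows <- do.call(rbind, lapply(scans, function(s) {
    data.frame(timestamp = s$timestamp, bssid = names(s$readings),
               rssi = unname(s$readings))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a calibration set from JSON
#'
#' Format: `{"fingerprints": [{"id": ..., "scans": [{"timestamp": ...,
#' "readings": {"<bssid>": <rssi>, ...}}, ...]}, ...]}`.
#'
#' @param path JSON file path.
#' @return List of [fingerprint()] objects.
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path)
  if (is.null(j$fingerprints)) stop("calibration JSON lacks 'fingerprints'")
  lapply(j$fingerprints, function(f) {
    scans <- lapply(f$scans, function(s) {
      rssi_scan(unlist(s$readings),
                timestamp = if (is.null(s$timestamp)) NA_real_ else s$timestamp)
    })
    fingerprint(f$id, scans)
  })
}

#' Write a calibration set to JSON
#'
#' @param fingerprints List of [fingerprint()] objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(fingerprints, path) {
  obj <- list(fingerprints = lapply(fingerprints, function(f) {
    list(id = f$id, scans = lapply(f$scans, function(s) {
      list(timestamp = s$timestamp, readings = as.list(s$readings))
    }))
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize / restore a calibration model
#'
#' The JSON carries the per-(fingerprint, BSSID) statistics, the global
#' BSSID set, the imputation floor and the full configuration echo, so a
#' restored model reproduces identical location estimates.
#'
#' @param model An `rssi_calibration` from [calibrate()].
#' @param path JSON path.
#' @return `write_model_json`: `path`, invisibly. `read_model_json`: the
#'   restored `rssi_calibration`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "rssi_calibration"))
  jsonlite::write_json(list(stats = model$stats,
                            fingerprints = model$fingerprints,
                            bssids = model$bssids, floor = model$floor,
                            config = model$config),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$stats$n <- as.integer(j$stats$n)
  j$config$imputed_n <- as.integer(j$config$imputed_n)
  structure(list(stats = j$stats, fingerprints = j$fingerprints,
                 bssids = j$bssids, floor = j$floor, config = j$config),
            class = "rssi_calibration")
}

#' Read / write accelerometer traces
#'
#' CSV with columns `t,x,y,z` (seconds, m/s^2), strictly increasing t.
#'
#' @param path CSV path.
#' @return `read_accel_csv`: the validated data.frame.
#' @export
read_accel_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t", "x", "y", "z") %in% names(df))) {
    stop("accelerometer CSV needs columns t,x,y,z")
  }
  bad <- which(!stats::complete.cases(df) |
                 !apply(as.matrix(df), 1, function(r) all(is.finite(r))))
  if (length(bad) > 0L) stop("non-finite accelerometer values at row ", bad[1])
  if (any(diff(df$t) <= 0)) stop("accelerometer timestamps not strictly increasing")
  df
}

#' @rdname read_accel_csv
#' @param trace data.frame with columns t,x,y,z.
#' @export
write_accel_csv <- function(trace, path) {
  utils::write.csv(trace[, c("t", "x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write single-lead ECG CSV
#'
#' Two-column `t,mv` (the rate is inferred from the median time step) or
#' single-column `mv` with an explicit `rate`.
#'
#' @param path CSV path.
#' @param rate Sampling rate in Hz; required for single-column files.
#' @return `read_ecg_csv`: an [ecg_signal()].
#' @export
read_ecg_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path)
  if (all(c("t", "mv") %in% names(df))) {
    if (is.null(rate)) rate <- 1 / stats::median(diff(df$t))
    ecg_signal(df$mv, rate)
  } else if ("mv" %in% names(df)) {
    if (is.null(rate)) stop("single-column ECG CSV requires an explicit rate")
    ecg_signal(df$mv, rate)
  } else stop("ECG CSV needs columns (t,mv) or (mv)")
}

#' @rdname read_ecg_csv
#' @param signal An [ecg_signal()].
#' @export
write_ecg_csv <- function(signal, path) {
  n <- length(signal$samples)
  utils::write.csv(data.frame(t = (seq_len(n) - 1) / signal$rate,
                              mv = signal$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write beat-feature tables
#'
#' Lossless round trip of the [beat_features()] columns (NA preserved).
#'
#' @param path CSV path.
#' @return `read_features_csv`: a `beat_features` data.frame.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "Pi", "Qi", "Ri", "Si", "Ti", "Dpq", "Dqr", "Drs", "Dst")
  if (!all(need %in% names(df))) {
    stop("features CSV lacks columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  class(df) <- c("beat_features", "data.frame")
  df
}

#' @rdname read_features_csv
#' @param features A `beat_features` data.frame.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' Read / write alerts as JSON lines
#'
#' One object per line: `{"type": ..., "time_ms": ..., "evidence": [...]}`.
#'
#' @param path File path.
#' @return `read_alerts_jsonl`: an `alerts` data.frame.
#' @export
read_alerts_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parsed <- lapply(lines, jsonlite::fromJSON)
  out <- data.frame(type = vapply(parsed, `[[`, character(1), "type"),
                    time_ms = vapply(parsed, `[[`, numeric(1), "time_ms"))
  out$evidence <- lapply(parsed, function(p) as.numeric(p$evidence))
  class(out) <- c("alerts", "data.frame")
  out
}

#' @rdname read_alerts_jsonl
#' @param alerts An `alerts` data.frame from [evaluate_stream()].
#' @export
write_alerts_jsonl <- function(alerts, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(alerts))) {
    writeLines(jsonlite::toJSON(list(type = alerts$type[i],
                                     time_ms = alerts$time_ms[i],
                                     evidence = alerts$evidence[[i]]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

.known_pipeline_keys <- c("out", "seed", "calibration", "scans", "accel",
                          "ecg", "location", "steps", "rules", "monitor")

#' Run the full offline monitoring pipeline
#'
#' Executes calibrate -> locate over a scan stream, step detection over the
#' accelerometer trace, ECG beat detection -> rules, and the motion-gated
#' fusion loop, then writes a session log (JSON lines of
#' `{t, position, moving, alerts}`) and a config echo with all defaults
#' materialized into the output directory. Deterministic: identical inputs
#' and seed give byte-identical outputs.
#'
#' @param config Named list. Required: `out` (output directory),
#'   `calibration` (calibration JSON path or list of [fingerprint()]s),
#'   `scans` (scan-stream CSV path or list of scans), `accel` (CSV path or
#'   data.frame), `ecg` (list with `path` or `signal`, and `rate` for
#'   single-column files). Optional parameter blocks: `location`
#'   (k, sd_floor, imputed_n, quartile_type, residual_scale), `steps`
#'   (upper, lower, timeout_s), `rules` (fields of [rule_config()]),
#'   `monitor` (alert_dedup_s), `seed`. Unknown keys are rejected.
#' @return Invisibly, a list with `session` (data.frame), `features`,
#'   `alerts`, `steps`, `model`, and the paths written.
#' @export
run_pipeline <- function(config) {
  unknown <- setdiff(names(config), .known_pipeline_keys)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (key in c("out", "calibration", "scans", "accel", "ecg")) {
    if (is.null(config[[key]])) stop("config lacks required key '", key, "'")
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)

  loc <- utils::modifyList(list(k = 3L, sd_floor = 0.5, imputed_n = 2L,
                                quartile_type = 7,
                                residual_scale = "standard_error"),
                           if (is.null(config$location)) list() else config$location)
  stp <- do.call(step_config, if (is.null(config$steps)) list() else config$steps)
  rls <- do.call(rule_config, if (is.null(config$rules)) list() else config$rules)
  mon <- utils::modifyList(list(alert_dedup_s = 60),
                           if (is.null(config$monitor)) list() else config$monitor)

  fps <- if (is.character(config$calibration)) {
    read_calibration_json(config$calibration)
  } else config$calibration
  scans <- if (is.character(config$scans)) read_scan_stream(config$scans)
           else config$scans
  accel <- if (is.character(config$accel)) read_accel_csv(config$accel)
           else config$accel
  ecg <- if (!is.null(config$ecg$signal)) config$ecg$signal
         else read_ecg_csv(config$ecg$path, rate = config$ecg$rate)

  model <- calibrate(fps, sd_floor = loc$sd_floor, imputed_n = loc$imputed_n,
                     quartile_type = loc$quartile_type,
                     residual_scale = loc$residual_scale)
  steps <- detect_steps(accel, stp)

  env <- ecg_preprocess(ecg)
  r_idx <- detect_r_peaks(env, ecg)
  ann <- locate_waves(ecg, r_idx)
  features <- beat_features(ann, ecg$rate)
  alerts <- evaluate_stream(features, rls)

  track <- track_state(k = loc$k)
  mstate <- monitor_state(alert_dedup_s = mon$alert_dedup_s)
  mstate <- dispatch(alerts, mstate)
  session <- vector("list", length(scans))
  prev_t <- -Inf
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    res <- locate(s, model, track)
    track <- res$state
    mv <- motion_state(steps, s$timestamp, stp)
    mstate <- fuse(track, mv, mstate)
    in_window <- mstate$log$time_ms / 1000 > prev_t &
      mstate$log$time_ms / 1000 <= s$timestamp
    session[[i]] <- list(t = s$timestamp, position = mstate$position,
                         moving = mv == "moving",
                         alerts = as.list(mstate$log$type[in_window]))
    prev_t <- s$timestamp
  }

  session_path <- file.path(config$out, "session.jsonl")
  con <- file(session_path, open = "wt")
  for (row in session) {
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"), con)
  }
  close(con)

  echo <- list(seed = config$seed, location = loc,
               steps = unclass(stp), rules = unclass(rls), monitor = mon)
  echo_path <- file.path(config$out, "config_echo.json")
  jsonlite::write_json(echo, echo_path, auto_unbox = TRUE, digits = NA,
                       null = "null")

  write_features_csv(features, file.path(config$out, "features.csv"))
  write_alerts_jsonl(alerts, file.path(config$out, "alerts.jsonl"))
  utils::write.csv(steps, file.path(config$out, "steps.csv"), row.names = FALSE)

  invisible(list(session = session, features = features, alerts = alerts,
                 steps = steps, model = model,
                 paths = c(session = session_path, echo = echo_path)))
}
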