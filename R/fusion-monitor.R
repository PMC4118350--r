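#' Initial monitoring-loop state
#'
#' Holds the committed position (frozen while the wearer is stationary), and
#' an append-only alert log with per-type deduplication.
#'
#' @param alert_dedup_s Suppress repeated alerts of one type within this many
#'   seconds (default 60).
#' @return An object of class `monitor_state`.
#' @export
monitor_state <- function(alert_dedup_s = 60) {
  stopifnot(alert_dedup_s > 0)
  structure(list(position = NA_character_,
                 log = data.frame(type = character(0), time_ms = numeric(0)),
                 alert_dedup_s = alert_dedup_s),
            class = "monitor_state")
}

#' Gate a position update by motion state
#'
#' The committed fingerprint from the location tracker is adopted only while
#' the wearer is moving; while stationary the last position is frozen, which
#' keeps RSSI fluctuation from walking the position around an idle wearer.
#'
#' @param location_track A [track_state()].
#' @param motion `"moving"` or `"stationary"` (from [motion_state()]).
#' @param state A [monitor_state()].
#' @return The updated `monitor_state`.
#' @export
fuse <- function(location_track, motion, state) {
  stopifnot(inherits(location_track, "track_state"),
            inherits(state, "monitor_state"),
            motion %in% c("moving", "stationary"))
  if (motion == "moving" && !is.na(location_track$committed)) {
    state$position <- location_track$committed
  }
  state
}

#' Append alerts to the monitor log with deduplication
#'
#' Identical alert types within the dedup window of the last logged alert of
#' that type are dropped; everything else is appended in time order.
#'
#' @param alerts An `alerts` data.frame from [evaluate_stream()]
#'   (time-ordered).
#' @param state A [monitor_state()].
#' @return The updated `monitor_state`.
#' @export
dispatch <- function(alerts, state) {
  stopifnot(inherits(state, "monitor_state"))
  if (is.null(alerts) || nrow(alerts) == 0L) return(state)
  if (is.unsorted(alerts$time_ms)) stop("alerts must be time-ordered")
  win_ms <- state$alert_dedup_s * 1000
  for (i in seq_len(nrow(alerts))) {
    ty <- alerts$type[i]
    tm <- alerts$time_ms[i]
    prior <- state$log$time_ms[state$log$type == ty]
    if (length(prior) == 0L || tm - max(prior) > win_ms) {
      state$log <- rbind(state$log,
                         data.frame(type = ty, time_ms = tm))
    }
  }
  state
}
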