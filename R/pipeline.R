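#' Analyse a full recording session
#'
#' Splits a calibrated recording into trial segments, runs event detection
#' on each and computes per-segment metrics: the complete per-session
#' analysis from raw gaze to the per-segment metric rows that condition
#' summaries are built from.
#'
#' @param recording A [gaze_recording()] (already zero-point calibrated, or
#'   supply `calibrate = TRUE` with manifest calibration windows).
#' @param manifest A [trial_manifest()].
#' @param params A [detection_params()].
#' @param calibrate Apply [calibrate_zero()] using the manifest's
#'   calibration windows first (default `FALSE`).
#' @param participant,session Identifier labels attached to the metric rows.
#' @return An object of class `fem_session`: list with `segments` (each a
#'   list of `segment`, `events`, `metrics`), and `metrics_table` (one row
#'   per segment with identifiers, ready for [aggregate_conditions()]).
#' @export
analyze_session <- function(recording, manifest, params = detection_params(),
                            calibrate = FALSE, participant = "P1",
                            session = 1L) {
  if (calibrate) {
    if (is.null(manifest$calibration_windows))
      stop_fem_config("calibrate = TRUE needs calibration windows in the manifest")
    recording <- apply_calibration(
      recording, calibrate_zero(recording, manifest$calibration_windows))
  }
  segments <- split_segments(recording, manifest)
  out <- lapply(segments, function(seg) {
    ev <- detect_events(seg, params)
    met <- segment_metrics(ev)
    list(segment = seg, events = ev, metrics = met)
  })
  tab <- do.call(rbind, lapply(out, function(s) {
    cbind(data.frame(participant = participant, session = session,
                     label = s$segment$label, polarity = s$segment$polarity),
          s$metrics$means)
  }))
  rownames(tab) <- NULL
  structure(list(segments = out, metrics_table = tab),
            class = "fem_session")
}

#' @export
print.fem_session <- function(x, ...) {
  cat(sprintf("Analysed session: %d segment(s)\n", length(x$segments)))
  print(x$metrics_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write detected events as CSV
#'
#' One row per event: type (`saccade`/`drift`), indices, times, kinematics
#' where applicable, and discard status and reason for candidates that were
#' dropped or excluded.
#'
#' @param events An `fem_events` object.
#' @param path Output path.
#' @return The events table, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "fem_events"))
  s <- events$saccades; d <- events$drifts
  rows <- list()
  if (nrow(s) > 0)
    rows$s <- data.frame(type = "saccade",
                         onset_idx = s$onset_idx, offset_idx = s$offset_idx,
                         onset_t = s$onset_t, offset_t = s$offset_t,
                         dx = s$dx, dy = s$dy, magnitude = s$magnitude,
                         direction = s$direction, peak_speed = s$peak_speed,
                         duration = s$offset_t - s$onset_t,
                         discarded = FALSE, discard_reason = "")
  if (nrow(d) > 0)
    rows$d <- data.frame(type = "drift",
                         onset_idx = d$start_idx, offset_idx = d$end_idx,
                         onset_t = d$start_t, offset_t = d$end_t,
                         dx = NA_real_, dy = NA_real_, magnitude = NA_real_,
                         direction = NA_real_, peak_speed = NA_real_,
                         duration = d$duration,
                         discarded = FALSE, discard_reason = "")
  dc <- events$discards
  if (nrow(dc) > 0)
    rows$dc <- data.frame(type = dc$type, onset_idx = NA_integer_,
                          offset_idx = NA_integer_, onset_t = dc$onset_t,
                          offset_t = dc$offset_t, dx = NA_real_,
                          dy = NA_real_, magnitude = NA_real_,
                          direction = NA_real_, peak_speed = NA_real_,
                          duration = dc$offset_t - dc$onset_t,
                          discarded = TRUE, discard_reason = dc$reason)
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(type = character(), onset_idx = integer(),
                      offset_idx = integer(), onset_t = numeric(),
                      offset_t = numeric(), dx = numeric(), dy = numeric(),
                      magnitude = numeric(), direction = numeric(),
                      peak_speed = numeric(), duration = numeric(),
                      discarded = logical(), discard_reason = character())
  tab <- tab[order(tab$onset_t), , drop = FALSE]
  rownames(tab) <- NULL
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Saccade displacement vectors of a session
#'
#' Collects the (dx, dy) displacement vectors of selected saccades (or the
#' first-to-last displacement of drift episodes) across segments, as input
#' for [kde2d_map()].
#'
#' @param session An `fem_session` from [analyze_session()].
#' @param type `"saccade"` or `"drift"`.
#' @return Two-column matrix of displacement vectors (deg).
#' @export
displacement_vectors <- function(session, type = c("saccade", "drift")) {
  type <- match.arg(type)
  do.call(rbind, lapply(session$segments, function(s) {
    if (type == "saccade") {
      sc <- s$events$saccades
      if (nrow(sc) == 0) return(NULL)
      cbind(dx = sc$dx, dy = sc$dy)
    } else {
      d <- s$events$drifts
      if (nrow(d) == 0) return(NULL)
      rec <- as_gaze_recording(s$segment)
      cbind(dx = rec$x[d$end_idx] - rec$x[d$start_idx],
            dy = rec$y[d$end_idx] - rec$y[d$start_idx])
    }
  }))
}
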