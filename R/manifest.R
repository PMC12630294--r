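#' Trial manifest
#'
#' Describes the trial schedule of a recording session: one row per fixation
#' trial (target design, polarity, onset/offset, target center) plus the
#' central-fixation intervals used for zero-point calibration. Trials follow
#' the half-open interval convention `[t_on, t_off)`.
#'
#' @param trials A data frame with columns `label` (target design, e.g. one
#'   of Gaussian, Bessel, Circle, Point, CCP), `polarity` (e.g.
#'   `"black-on-grey"` or `"white-on-black"`), `t_on`, `t_off` (seconds) and
#'   `cx`, `cy` (target center, degrees).
#' @param calibration_windows Optional two-column matrix (or list of length-2
#'   vectors) of `(t_start, t_end)` intervals of central fixation.
#' @param trial_duration Expected trial duration in seconds (default 30).
#'
#' @return An object of class `trial_manifest`.
#' @export
trial_manifest <- function(trials, calibration_windows = NULL,
                           trial_duration = 30) {
  trials <- as.data.frame(trials)
  need <- c("label", "polarity", "t_on", "t_off", "cx", "cy")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols) > 0)
    stop_fem_format(sprintf("manifest trials lack column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  if (nrow(trials) > 0) {
    trials <- trials[order(trials$t_on), , drop = FALSE]
    rownames(trials) <- NULL
    if (any(trials$t_off <= trials$t_on))
      stop_fem_config("each trial needs t_off > t_on")
    if (nrow(trials) > 1 &&
        any(trials$t_on[-1] < trials$t_off[-nrow(trials)]))
      stop_fem_config("trials must not overlap")
  }
  if (!is.null(calibration_windows)) {
    calibration_windows <- if (is.list(calibration_windows))
      do.call(rbind, lapply(calibration_windows,
                            function(w) as.numeric(unlist(w))[1:2]))
    else matrix(as.numeric(calibration_windows), ncol = 2)
    if (any(calibration_windows[, 2] <= calibration_windows[, 1]))
      stop_fem_config("calibration windows need t_end > t_start")
  }
  structure(list(trials = trials,
                 calibration_windows = calibration_windows,
                 trial_duration = trial_duration),
            class = "trial_manifest")
}

#' @export
print.trial_manifest <- function(x, ...) {
  cat(sprintf("Trial manifest: %d trials of %g s, %d calibration window(s)\n",
              nrow(x$trials), x$trial_duration,
              if (is.null(x$calibration_windows)) 0L
              else nrow(x$calibration_windows)))
  if (nrow(x$trials) > 0) print(x$trials)
  invisible(x)
}

#' Read or write a trial manifest (JSON)
#'
#' @param path File path.
#' @return `read_manifest()` returns a [trial_manifest()];
#'   `write_manifest()` invisibly returns `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_fem_data(sprintf("manifest not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trial_manifest(trials = as.data.frame(obj$trials),
                 calibration_windows = obj$calibration_windows,
                 trial_duration = obj$trial_duration %||% 30)
}

#' @rdname read_manifest
#' @param manifest A [trial_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "trial_manifest"))
  jsonlite::write_json(list(trials = manifest$trials,
                            calibration_windows = manifest$calibration_windows,
                            trial_duration = manifest$trial_duration),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a recording into per-trial segments
#'
#' Assigns samples to trials by the half-open convention
#' `t_on <= t < t_off`; a sample exactly at `t_off` belongs to the next
#' interval only, so no sample is ever assigned to two segments.
#'
#' @param recording A [gaze_recording()].
#' @param manifest A [trial_manifest()].
#' @return A list of `gaze_segment` objects; each holds the recording slice,
#'   the trial `label`, `polarity`, target `center` and the index range
#'   `idx` into the parent recording.
#' @export
split_segments <- function(recording, manifest) {
  stopifnot(inherits(recording, "gaze_recording"),
            inherits(manifest, "trial_manifest"))
  trials <- manifest$trials
  if (nrow(trials) == 0) return(list())
  n <- length(recording$t)
  med_dt <- if (n > 1) stats::median(diff(recording$t)) else
    1 / recording$nominal_rate
  lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    if (tr$t_on < recording$t[1] - med_dt / 2 ||
        tr$t_off > recording$t[n] + med_dt)
      stop_fem_data(sprintf(
        "trial %d [%g, %g) extends beyond the recording [%g, %g]",
        i, tr$t_on, tr$t_off, recording$t[1], recording$t[n]))
    idx <- which(recording$t >= tr$t_on & recording$t < tr$t_off)
    if (length(idx) == 0)
      stop_fem_data(sprintf("trial %d contains no samples", i))
    dur <- diff(range(recording$t[idx])) + med_dt
    if (abs(dur - manifest$trial_duration) > med_dt * 1.5)
      warning(sprintf("segment %d duration %.4f s differs from manifest %g s",
                      i, dur, manifest$trial_duration))
    structure(list(
      recording = gaze_recording(recording$t[idx], recording$x[idx],
                                 recording$y[idx], recording$valid[idx],
                                 recording$nominal_rate),
      label = tr$label, polarity = tr$polarity,
      center = c(tr$cx, tr$cy),
      idx = range(idx), t_on = tr$t_on, t_off = tr$t_off),
      class = "gaze_segment")
  })
}

#' @export
print.gaze_segment <- function(x, ...) {
  cat(sprintf("Segment '%s' (%s), center (%g, %g) deg, [%g, %g) s, %d samples\n",
              x$label, x$polarity, x$center[1], x$center[2],
              x$t_on, x$t_off, length(x$recording$t)))
  invisible(x)
}
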