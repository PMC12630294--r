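#' Zero-point calibration from central fixations
#'
#' The retinal tracker needs no gain calibration, only a zero point. The
#' offset is the robust center (per-axis median) of all valid samples pooled
#' across the central-fixation calibration windows. The first 0.5 s of each
#' window is discarded as settle time, so the saccade acquiring the
#' calibration target does not bias the estimate; the median makes the
#' estimate robust to any remaining saccades within the windows.
#'
#' @param recording A [gaze_recording()].
#' @param windows Two-column matrix (or list of `(t_start, t_end)` pairs) of
#'   calibration intervals, half-open in time.
#' @param settle Seconds discarded from the start of each window (default
#'   0.5).
#' @param min_samples Minimum valid samples required per window after the
#'   settle discard (default 50); fewer triggers a warning, none anywhere an
#'   error.
#'
#' @return Numeric `c(x, y)` offset in degrees: the location that
#'   [apply_calibration()] maps to the origin.
#' @seealso [apply_calibration()]
#' @export
calibrate_zero <- function(recording, windows, settle = 0.5,
                           min_samples = 50) {
  stopifnot(inherits(recording, "gaze_recording"))
  if (is.list(windows))
    windows <- do.call(rbind, lapply(windows,
                                     function(w) as.numeric(unlist(w))[1:2]))
  windows <- matrix(as.numeric(windows), ncol = 2)
  keep <- logical(length(recording$t))
  for (i in seq_len(nrow(windows))) {
    sel <- recording$t >= windows[i, 1] + settle &
      recording$t < windows[i, 2] & recording$valid
    if (sum(sel) < min_samples)
      warning(sprintf(
        "calibration window %d has only %d valid samples after settle time",
        i, sum(sel)))
    keep <- keep | sel
  }
  if (!any(keep))
    stop_fem_data("no valid samples in any calibration window")
  c(stats::median(recording$x[keep]), stats::median(recording$y[keep]))
}

#' Subtract a zero-point offset from a recording
#'
#' @param recording A [gaze_recording()].
#' @param offset Numeric `c(x, y)` in degrees, typically from
#'   [calibrate_zero()].
#' @return The recording translated so the offset becomes the origin.
#' @export
apply_calibration <- function(recording, offset) {
  stopifnot(inherits(recording, "gaze_recording"), length(offset) == 2)
  recording$x <- recording$x - offset[1]
  recording$y <- recording$y - offset[2]
  recording
}
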