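#' Sample-to-sample RMS deviation (RMS-S2S)
#'
#' The standard precision metric of an eye tracker: the root mean square of
#' Euclidean displacements between consecutive samples,
#' \eqn{\sqrt{\mathrm{mean}(\Delta x^2 + \Delta y^2)}}, reported in arcmin.
#' Pairs that span an invalid sample are skipped rather than interpolated,
#' so data loss never fabricates displacements.
#'
#' @param obj A [gaze_recording()] or [gaze_segment].
#' @return RMS-S2S in arcmin.
#' @export
#' @examples
#' rec <- gaze_recording((0:99) / 620, rep(0, 100), rep(0, 100))
#' rms_s2s(rec)  # 0: constant position
rms_s2s <- function(obj) {
  rec <- as_gaze_recording(obj)
  n <- length(rec$t)
  if (n < 2)
    stop_fem_data("RMS-S2S needs at least two samples")
  ok <- rec$valid[-n] & rec$valid[-1]
  if (!any(ok))
    stop_fem_data("RMS-S2S undefined: no consecutive valid sample pair")
  dx <- diff(rec$x)[ok]
  dy <- diff(rec$y)[ok]
  sqrt(mean(dx^2 + dy^2)) * 60
}

#' Fraction of samples lost
#'
#' Fraction of samples for which no gaze position could be determined
#' (invalid samples, including blinks), in \[0, 1\].
#'
#' @param obj A [gaze_recording()] or [gaze_segment].
#' @return Numeric fraction.
#' @export
data_loss_fraction <- function(obj) {
  rec <- as_gaze_recording(obj)
  if (length(rec$t) == 0)
    stop_fem_data("data loss undefined for an empty recording")
  mean(!rec$valid)
}

#' Data-quality report
#'
#' @param obj A [gaze_recording()] or [gaze_segment].
#' @return A list of class `fem_quality` with `rms_s2s` (arcmin),
#'   `data_loss` (fraction) and `n_samples`.
#' @export
quality_report <- function(obj) {
  rec <- as_gaze_recording(obj)
  structure(list(rms_s2s = rms_s2s(rec),
                 data_loss = data_loss_fraction(rec),
                 n_samples = length(rec$t)),
            class = "fem_quality")
}

#' @export
print.fem_quality <- function(x, ...) {
  cat(sprintf("RMS-S2S: %.4g arcmin; data loss: %.2f%%; %d samples\n",
              x$rms_s2s, 100 * x$data_loss, x$n_samples))
  invisible(x)
}

#' Write a quality report as JSON
#'
#' @param report An `fem_quality` object.
#' @param path Output path.
#' @export
write_quality <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

as_gaze_recording <- function(obj) {
  if (inherits(obj, "gaze_recording")) return(obj)
  if (inherits(obj, "gaze_segment")) return(obj$recording)
  stop_fem_data("expected a gaze_recording or gaze_segment")
}
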