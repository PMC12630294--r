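#' Construct a gaze recording
#'
#' A gaze recording is the raw substrate of all analysis stages: a
#' monotonically sampled time series of gaze positions in degrees of visual
#' angle, with a per-sample validity flag. Samples with non-finite positions
#' are marked invalid (positions are retained as `NA`, never fabricated).
#'
#' The coordinate convention is participant-view: degrees of visual angle,
#' `+x` rightward, `+y` upward, origin at the calibrated zero point.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y Numeric vectors of horizontal/vertical gaze position in degrees.
#' @param valid Optional logical vector; samples with non-finite `x` or `y`
#'   are forced invalid regardless.
#' @param nominal_rate Nominal sampling rate in Hz (default 620). A warning
#'   is issued when the median sample interval deviates from `1/nominal_rate`
#'   by more than 20%.
#'
#' @return An object of class `gaze_recording`: a list with elements `t`,
#'   `x`, `y`, `valid` (all the same length) and `nominal_rate`.
#' @export
#' @examples
#' rec <- gaze_recording(t = (0:9) / 620, x = rnorm(10, sd = 0.01),
#'                       y = rnorm(10, sd = 0.01))
#' rec
gaze_recording <- function(t, x, y, valid = NULL, nominal_rate = 620) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (length(x) != n || length(y) != n)
    stop_fem_data("t, x and y must have the same length")
  if (n > 1) {
    dt <- diff(t)
    bad <- which(dt <= 0)
    if (length(bad) > 0)
      stop_fem_data(sprintf(
        "timestamps must be strictly increasing; first violation at sample %d",
        bad[1] + 1L))
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- as.logical(valid)
  if (length(valid) != n)
    stop_fem_data("valid must match the length of t")
  valid[is.na(valid)] <- FALSE
  valid <- valid & is.finite(x) & is.finite(y)
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1 ||
      !is.finite(nominal_rate) || nominal_rate <= 0)
    stop_fem_config("nominal_rate must be a positive number")
  if (n > 1) {
    med_dt <- stats::median(diff(t))
    if (abs(med_dt - 1 / nominal_rate) > 0.2 / nominal_rate)
      warning(sprintf(
        "median sample interval %.6f s deviates more than 20%% from nominal 1/%g s",
        med_dt, nominal_rate))
  }
  structure(list(t = t, x = x, y = y, valid = valid,
                 nominal_rate = nominal_rate),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("Gaze recording: %d samples, %.2f s at %g Hz nominal\n",
              n, if (n > 0) diff(range(x$t)) else 0, x$nominal_rate))
  cat(sprintf("  data loss: %.2f%%\n", 100 * data_loss_fraction(x)))
  invisible(x)
}

#' @export
as.data.frame.gaze_recording <- function(x, ...) {
  data.frame(t_s = x$t, x_deg = x$x, y_deg = x$y,
             valid = as.integer(x$valid))
}

#' @export
length.gaze_recording <- function(x) length(x$t)

#' Read a gaze recording from delimited text
#'
#' Reads the canonical gaze dialect: a delimited text file with a header and
#' columns for time (seconds), horizontal and vertical gaze (degrees) and an
#' optional 0/1 validity column. Samples with blank or non-finite positions
#' are marked invalid; their positions are retained as missing.
#'
#' @param path Path to the file.
#' @param dialect A list describing the on-disk format: `sep` (default `","`)
#'   and the column names `time`, `x`, `y`, `valid` (defaults `"t_s"`,
#'   `"x_deg"`, `"y_deg"`, `"valid"`). Adapter dialects for other column
#'   layouts map onto this canonical form.
#' @param nominal_rate Nominal sampling rate in Hz.
#'
#' @return A [gaze_recording()].
#' @seealso [write_gaze()]
#' @export
read_gaze <- function(path, dialect = gaze_dialect(), nominal_rate = 620) {
  if (!file.exists(path))
    stop_fem_data(sprintf("gaze file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          stringsAsFactors = FALSE)
  need <- c(dialect$time, dialect$x, dialect$y)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop_fem_format(sprintf("missing required column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  valid <- if (dialect$valid %in% names(df))
    as.logical(as.numeric(df[[dialect$valid]])) else NULL
  gaze_recording(t = as.numeric(df[[dialect$time]]),
                 x = suppressWarnings(as.numeric(df[[dialect$x]])),
                 y = suppressWarnings(as.numeric(df[[dialect$y]])),
                 valid = valid, nominal_rate = nominal_rate)
}

#' Canonical gaze file dialect
#'
#' @param sep Field separator.
#' @param time,x,y,valid Column names in the file.
#' @return A list usable as the `dialect` argument of [read_gaze()] and
#'   [write_gaze()].
#' @export
gaze_dialect <- function(sep = ",", time = "t_s", x = "x_deg", y = "y_deg",
                         valid = "valid") {
  list(sep = sep, time = time, x = x, y = y, valid = valid)
}

#' Write a gaze recording as delimited text
#'
#' Writes the canonical dialect (`t_s,x_deg,y_deg,valid`). Positions are
#' written at full double precision so that a write/read round trip
#' reproduces the recording exactly.
#'
#' @param recording A [gaze_recording()].
#' @param path Output path.
#' @param dialect See [gaze_dialect()].
#' @export
write_gaze <- function(recording, path, dialect = gaze_dialect()) {
  stopifnot(inherits(recording, "gaze_recording"))
  df <- as.data.frame(recording)
  names(df) <- c(dialect$time, dialect$x, dialect$y, dialect$valid)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# condition helpers: config errors (exit 2 at the CLI), data errors (exit 3)
stop_fem_format <- function(msg)
  stop(errorCondition(msg, class = c("fem_format_error", "fem_data_error")))
stop_fem_data <- function(msg)
  stop(errorCondition(msg, class = "fem_data_error"))
stop_fem_config <- function(msg)
  stop(errorCondition(msg, class = "fem_config_error"))
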