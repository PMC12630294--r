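#' Gaze positions pooled over selected events
#'
#' Concatenates the valid gaze samples that lie inside the selected
#' (post-exclusion) microsaccade intervals and drift episodes. Warm-up
#' time, excluded events and data loss therefore never contribute to the
#' BCEA.
#'
#' @param events An `fem_events` object from [detect_events()], or a list
#'   with `saccades` and `drifts` data frames plus a `segment`.
#' @param segment Optional `gaze_segment`/[gaze_recording()] overriding
#'   `events$segment`.
#' @return Two-column matrix of positions (deg).
#' @export
pooled_positions <- function(events, segment = NULL) {
  rec <- as_gaze_recording(segment %||% events$segment)
  idx <- integer(0)
  s <- events$saccades
  if (nrow(s) > 0)
    idx <- c(idx, unlist(mapply(seq, s$onset_idx, s$offset_idx,
                                SIMPLIFY = FALSE)))
  d <- events$drifts
  if (nrow(d) > 0)
    idx <- c(idx, unlist(mapply(seq, d$start_idx, d$end_idx,
                                SIMPLIFY = FALSE)))
  idx <- sort(idx)
  idx <- idx[rec$valid[idx]]
  cbind(x = rec$x[idx], y = rec$y[idx])
}

#' Displacement magnitude and direction between two gaze samples
#'
#' @param p_from,p_to Numeric `c(x, y)` positions in degrees.
#' @return Named numeric `c(magnitude, direction)`: Euclidean distance in
#'   degrees and direction in degrees within \[0, 360) (0 = rightward,
#'   90 = upward).
#' @export
displacement_and_direction <- function(p_from, p_to) {
  dx <- p_to[1] - p_from[1]; dy <- p_to[2] - p_from[2]
  c(magnitude = sqrt(dx^2 + dy^2), direction = direction_deg(dx, dy))
}

#' Drift path length
#'
#' Sum of Euclidean distances between adjacent samples of a drift episode:
#' the meandering length of the drift trajectory, always at least as large
#' as its net displacement.
#'
#' @param x,y Episode sample positions (deg).
#' @return Path length in degrees.
#' @export
drift_path_length <- function(x, y) {
  if (length(x) < 2)
    stop_fem_data("path length needs at least 2 samples")
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Drift speed
#'
#' Mean magnitude of the gaze velocity during a drift episode. Per-axis
#' velocities are obtained from the gradient of the position signal using
#' second-order central differences at interior samples and one-sided
#' differences at the two boundary samples.
#'
#' @param x,y Episode sample positions (deg).
#' @param t Episode sample times (s).
#' @return Mean speed in deg/s.
#' @export
drift_speed <- function(x, y, t) {
  if (length(x) < 3)
    stop_fem_data("drift speed needs at least 3 samples")
  vx <- pracma::gradient(x, t)
  vy <- pracma::gradient(y, t)
  mean(sqrt(vx^2 + vy^2))
}

#' Microsaccade rate
#'
#' @param n_selected Number of selected microsaccades.
#' @param analyzed_duration Analysed duration in seconds (segment duration
#'   minus warm-up).
#' @return Rate in Hz.
#' @export
saccade_rate <- function(n_selected, analyzed_duration) {
  if (analyzed_duration <= 0)
    stop_fem_data("analyzed_duration must be positive")
  n_selected / analyzed_duration
}

#' Per-segment fixational eye-movement metrics
#'
#' Computes, from the selected events of one segment: the BCEA over the
#' pooled gaze positions, the microsaccade rate (count divided by segment
#' duration minus warm-up), per-saccade displacement and direction
#' (pre-onset to post-offset samples), and per-drift displacement,
#' direction (first to last episode sample), path length and mean speed.
#'
#' @param events An `fem_events` object from [detect_events()].
#' @param coverage_P BCEA coverage (default 0.6827).
#' @return An object of class `segment_metrics`: a list with `bcea`,
#'   `saccade_rate`, per-event metric vectors, `analyzed_duration`, and a
#'   one-row `means` data frame used for aggregation.
#' @export
segment_metrics <- function(events, coverage_P = 0.6827) {
  stopifnot(inherits(events, "fem_events"))
  rec <- as_gaze_recording(events$segment)
  params <- events$params
  seg_duration <- diff(range(rec$t)) + stats::median(diff(rec$t))
  analyzed <- seg_duration - params$warmup
  s <- events$saccades; d <- events$drifts
  b <- tryCatch(bcea(pooled_positions(events), coverage_P),
                fem_data_error = function(e) NULL)
  drift_disp <- drift_dir <- drift_pl <- drift_sp <- numeric(nrow(d))
  for (k in seq_len(nrow(d))) {
    idx <- d$start_idx[k]:d$end_idx[k]
    dd <- displacement_and_direction(
      c(rec$x[idx[1]], rec$y[idx[1]]),
      c(rec$x[idx[length(idx)]], rec$y[idx[length(idx)]]))
    drift_disp[k] <- dd["magnitude"]; drift_dir[k] <- dd["direction"]
    drift_pl[k] <- drift_path_length(rec$x[idx], rec$y[idx])
    drift_sp[k] <- drift_speed(rec$x[idx], rec$y[idx], rec$t[idx])
  }
  rate <- saccade_rate(nrow(s), analyzed)
  means <- data.frame(
    bcea = if (is.null(b)) NA_real_ else b$area,
    saccade_rate = rate,
    saccade_displacement = if (nrow(s)) mean(s$magnitude) else NA_real_,
    drift_displacement = if (nrow(d)) mean(drift_disp) else NA_real_,
    drift_path_length = if (nrow(d)) mean(drift_pl) else NA_real_,
    drift_speed = if (nrow(d)) mean(drift_sp) else NA_real_,
    rms_s2s = rms_s2s(rec),
    data_loss = data_loss_fraction(rec))
  structure(list(bcea = b, saccade_rate = rate,
                 saccade_displacements = s$magnitude,
                 saccade_directions = s$direction,
                 drift_displacements = drift_disp,
                 drift_directions = drift_dir,
                 drift_path_lengths = drift_pl,
                 drift_speeds = drift_sp,
                 analyzed_duration = analyzed,
                 means = means),
            class = "segment_metrics")
}

#' @export
print.segment_metrics <- function(x, ...) {
  cat(sprintf("Segment metrics over %.2f s analysed:\n", x$analyzed_duration))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Aggregate per-segment metrics to condition summaries
#'
#' Averages metric values within participant x target x polarity across
#' sessions (per-event metrics having already been averaged within each
#' segment), then takes the unweighted mean across participants so each
#' participant counts once in the grand means.
#'
#' @param seg_table Data frame with columns `participant`, `session`,
#'   `label`, `polarity` and one column per metric (e.g. the `means` rows
#'   of [segment_metrics()] bound together).
#' @param metrics Character vector of metric columns to aggregate (default:
#'   every numeric column that is not an identifier).
#' @return An object of class `fem_summary`: a list with `participant`
#'   (per participant x target x polarity means) and `grand` (across
#'   participants). Missing participant x condition cells are reported via
#'   a warning, never silently dropped.
#' @export
aggregate_conditions <- function(seg_table, metrics = NULL) {
  seg_table <- as.data.frame(seg_table)
  ids <- c("participant", "session", "label", "polarity")
  missing_cols <- setdiff(ids, names(seg_table))
  if (length(missing_cols) > 0)
    stop_fem_format(sprintf("segment table lacks column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  if (is.null(metrics))
    metrics <- setdiff(names(seg_table)[vapply(seg_table, is.numeric,
                                               logical(1))], ids)
  by_part <- stats::aggregate(
    seg_table[metrics],
    by = seg_table[c("participant", "label", "polarity")],
    FUN = function(v) mean(v, na.rm = TRUE))
  full <- expand.grid(participant = unique(seg_table$participant),
                      label = unique(seg_table$label),
                      polarity = unique(seg_table$polarity),
                      stringsAsFactors = FALSE)
  got <- paste(by_part$participant, by_part$label, by_part$polarity)
  want <- paste(full$participant, full$label, full$polarity)
  if (length(setdiff(want, got)) > 0)
    warning(sprintf("missing participant x condition cell(s): %s",
                    paste(setdiff(want, got), collapse = "; ")))
  grand <- stats::aggregate(by_part[metrics],
                            by = by_part[c("label", "polarity")],
                            FUN = function(v) mean(v, na.rm = TRUE))
  overall <- colMeans(
    stats::aggregate(by_part[metrics], by = by_part["participant"],
                     FUN = function(v) mean(v, na.rm = TRUE))[metrics],
    na.rm = TRUE)
  structure(list(participant = by_part, grand = grand, overall = overall),
            class = "fem_summary")
}

#' @export
print.fem_summary <- function(x, ...) {
  cat("Condition grand means (unweighted across participants):\n")
  print(x$grand, row.names = FALSE, digits = 4)
  invisible(x)
}
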