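#' Microsaccade detection parameters
#'
#' Parameters of the Engbert-Kliegl velocity-threshold detector and of the
#' event-level rules applied around it. The defaults are the conventional
#' toolbox defaults for the detector (5-sample velocity window, 3-sample
#' minimum event duration, per-axis median-based noise estimate with an
#' elliptic threshold combination) together with the event rules used for
#' 30-s fixation trials: candidates closer than 20 ms are merged, events
#' with pre-to-post displacement under 4 arcmin are discarded,
#' inter-saccadic intervals longer than 100 ms and free of data loss are
#' coded as drift episodes, the first half second of a segment is treated as
#' warm-up, and events further than 2.5 deg from the target center are
#' excluded.
#'
#' @param lambda_thresh Threshold multiplier \eqn{\lambda} on the
#'   median-based velocity noise estimate (default 6).
#' @param velocity_window Moving-average velocity window in samples (odd,
#'   default 5).
#' @param min_duration Minimum supra-threshold run length in samples
#'   (default 3).
#' @param merge_gap Candidates closer together than this gap in seconds are
#'   merged (default 0.020).
#' @param min_displacement Minimum saccade displacement in arcmin, applied
#'   after merging (default 4).
#' @param warmup Seconds discarded at the start of each segment (default
#'   0.5).
#' @param exclusion_radius Maximum distance from the target center in
#'   degrees for an event to be retained (default 2.5).
#' @param min_drift_duration Minimum drift-episode duration in seconds
#'   (default 0.100); episodes must be strictly longer.
#'
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(lambda_thresh = 6, velocity_window = 5,
                             min_duration = 3, merge_gap = 0.020,
                             min_displacement = 4, warmup = 0.5,
                             exclusion_radius = 2.5,
                             min_drift_duration = 0.100) {
  p <- list(lambda_thresh = lambda_thresh,
            velocity_window = as.integer(velocity_window),
            min_duration = as.integer(min_duration),
            merge_gap = merge_gap, min_displacement = min_displacement,
            warmup = warmup, exclusion_radius = exclusion_radius,
            min_drift_duration = min_drift_duration)
  if (any(vapply(p, function(v) !is.finite(v) || v <= 0, logical(1))))
    stop_fem_config("all detection parameters must be strictly positive")
  if (p$velocity_window %% 2L == 0L)
    stop_fem_config("velocity_window must be odd")
  structure(p, class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Detection parameters:\n")
  cat(sprintf("  lambda %g, velocity window %d samples, min duration %d samples\n",
              x$lambda_thresh, x$velocity_window, x$min_duration))
  cat(sprintf("  merge gap %g ms, min displacement %g arcmin\n",
              1000 * x$merge_gap, x$min_displacement))
  cat(sprintf("  warm-up %g s, exclusion radius %g deg, min drift %g ms\n",
              x$warmup, x$exclusion_radius, 1000 * x$min_drift_duration))
  invisible(x)
}

#' Smoothed gaze velocity (Engbert-Kliegl transform)
#'
#' Computes the per-axis moving-average velocity used by the
#' velocity-threshold detector. For the default 5-sample window,
#' \deqn{v_n = (p_{n+2} + p_{n+1} - p_{n-1} - p_{n-2}) / (6\,\Delta t)}
#' with \eqn{\Delta t} the segment's median sample interval (robust to
#' timing jitter; the stencil assumes uniform sampling). The velocity is
#' undefined wherever the stencil touches an invalid or out-of-range
#' sample; velocities adjacent to data loss are never interpolated.
#'
#' @param segment A `gaze_segment` or [gaze_recording()].
#' @param params A [detection_params()].
#' @return A list of class `velocity_series` with `vx`, `vy` (deg/s,
#'   aligned to samples), logical `defined`, and `dt` (the median sample
#'   interval used).
#' @export
compute_velocity <- function(segment, params = detection_params()) {
  rec <- as_gaze_recording(segment)
  n <- length(rec$t)
  w <- params$velocity_window
  if (n < w)
    stop_fem_data(sprintf("segment of %d samples is shorter than the %d-sample velocity window",
                          n, w))
  dt <- stats::median(diff(rec$t))
  half <- (w - 1L) %/% 2L
  # generalized EK stencil: sum of leading minus trailing positions
  denom <- 2 * sum(seq_len(half)) * dt   # window 5 -> 6*dt
  shift <- function(v, k) {             # v displaced by k samples, NA-padded
    if (k > 0) c(v[-seq_len(k)], rep(NA_real_, k))
    else c(rep(NA_real_, -k), v[seq_len(n + k)])
  }
  stencil <- function(p) {
    acc <- rep(0, n)
    for (k in seq_len(half)) acc <- acc + shift(p, k) - shift(p, -k)
    acc / denom
  }
  x <- ifelse(rec$valid, rec$x, NA_real_)
  y <- ifelse(rec$valid, rec$y, NA_real_)
  vx <- stencil(x); vy <- stencil(y)
  # defined only where every sample under the stencil is valid and in range
  bad <- cumsum(c(0L, !rec$valid))
  i <- seq_len(n)
  defined <- i > half & i <= n - half
  lo <- pmax(i - half, 1L); hi <- pmin(i + half, n)
  defined <- defined & (bad[hi + 1L] - bad[lo] == 0L)
  vx[!defined] <- NA_real_; vy[!defined] <- NA_real_
  structure(list(vx = vx, vy = vy, defined = defined, dt = dt, t = rec$t),
            class = "velocity_series")
}

#' Median-based velocity thresholds
#'
#' Estimates the per-axis velocity noise level with the median estimator
#' \eqn{\sigma = \sqrt{\langle v^2\rangle_{med} - \langle v\rangle_{med}^2}}
#' and sets the elliptic detection threshold \eqn{\eta = \lambda\sigma} per
#' axis.
#'
#' @param vel A `velocity_series` from [compute_velocity()].
#' @param lambda_thresh Threshold multiplier (default 6).
#' @return A list of class `ek_thresholds` with `sigma_x`, `sigma_y`,
#'   `eta_x`, `eta_y` (deg/s).
#' @export
estimate_thresholds <- function(vel, lambda_thresh = 6) {
  v_ok_x <- vel$vx[vel$defined]; v_ok_y <- vel$vy[vel$defined]
  if (length(v_ok_x) < 10)
    stop_fem_data("need at least 10 defined velocity samples to estimate thresholds")
  sigma <- function(v) sqrt(max(stats::median(v^2) - stats::median(v)^2, 0))
  sx <- sigma(v_ok_x); sy <- sigma(v_ok_y)
  if (sx < 1e-9 || sy < 1e-9)
    stop_fem_data("degenerate velocity signal: median-based sigma is zero on an axis")
  structure(list(sigma_x = sx, sigma_y = sy,
                 eta_x = lambda_thresh * sx, eta_y = lambda_thresh * sy),
            class = "ek_thresholds")
}

#' Supra-threshold candidate runs
#'
#' Finds maximal runs of samples whose velocity exceeds the elliptic
#' criterion \eqn{(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1}, at least
#' `min_duration` samples long. Runs never span undefined velocity samples
#' (in particular, a data-loss run inside a candidate invalidates it).
#'
#' @param vel A `velocity_series`.
#' @param thr An `ek_thresholds`.
#' @param params A [detection_params()].
#' @return Integer matrix with columns `onset`, `offset` (inclusive sample
#'   indices), zero rows when nothing exceeds threshold.
#' @export
detect_candidates <- function(vel, thr, params = detection_params()) {
  crit <- (vel$vx / thr$eta_x)^2 + (vel$vy / thr$eta_y)^2 > 1
  crit[!vel$defined | is.na(crit)] <- FALSE
  runs <- rle(crit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= params$min_duration
  cbind(onset = starts[keep], offset = ends[keep])
}

#' Merge candidate saccades separated by short gaps
#'
#' Saccades closer together than `merge_gap` (end of one to start of the
#' next, in time) are merged into a single event, to avoid oscillations at
#' saccade end being detected as separate saccades. Applied iteratively to
#' a fixed point.
#'
#' @param intervals Integer matrix of `onset`/`offset` sample indices,
#'   ordered and disjoint.
#' @param t Sample timestamps (seconds).
#' @param merge_gap Gap threshold in seconds (default 0.020).
#' @return Merged interval matrix.
#' @export
merge_candidates <- function(intervals, t, merge_gap = 0.020) {
  if (is.null(dim(intervals)) || nrow(intervals) < 2) return(intervals)
  repeat {
    gaps <- t[intervals[-1, 1]] - t[intervals[-nrow(intervals), 2]]
    j <- which(gaps < merge_gap)
    if (length(j) == 0) break
    j <- j[1]
    intervals[j, 2] <- intervals[j + 1, 2]
    intervals <- intervals[-(j + 1), , drop = FALSE]
    if (nrow(intervals) < 2) break
  }
  intervals
}

#' Finalize saccade events
#'
#' Attaches kinematics to merged candidate intervals and applies the
#' minimum-displacement filter. Displacement is operationalized as the
#' vector from the last gaze sample before saccade onset to the first gaze
#' sample after saccade offset, so the dynamic overshoot at saccade end is
#' not counted. Events whose flanking samples are missing or invalid are
#' dropped and logged, as are events below `min_displacement`.
#'
#' @param segment A `gaze_segment` or [gaze_recording()].
#' @param intervals Merged interval matrix (sample indices into the
#'   segment).
#' @param params A [detection_params()].
#' @param vel Optional `velocity_series` (recomputed when absent) used for
#'   peak speed.
#' @return A list with `saccades` (data frame: `onset_idx`, `offset_idx`,
#'   `onset_t`, `offset_t`, `dx`, `dy`, `magnitude` (deg), `direction`
#'   (deg, 0 = rightward, 90 = upward), `peak_speed` (deg/s)) and
#'   `discards` (data frame of dropped candidates with reasons).
#' @export
finalize_saccades <- function(segment, intervals, params = detection_params(),
                              vel = NULL) {
  rec <- as_gaze_recording(segment)
  if (is.null(vel)) vel <- compute_velocity(rec, params)
  n <- length(rec$t)
  empty <- saccade_frame()
  discards <- discard_frame()
  if (is.null(dim(intervals)) || nrow(intervals) == 0)
    return(list(saccades = empty, discards = discards))
  rows <- vector("list", nrow(intervals))
  for (k in seq_len(nrow(intervals))) {
    on <- intervals[k, 1]; off <- intervals[k, 2]
    pre <- on - 1L; post <- off + 1L
    if (pre < 1L || post > n || !rec$valid[pre] || !rec$valid[post]) {
      discards <- rbind(discards, discard_row("saccade", rec$t[on], rec$t[off],
                                              "no_flanking_sample"))
      next
    }
    dx <- rec$x[post] - rec$x[pre]
    dy <- rec$y[post] - rec$y[pre]
    mag <- sqrt(dx^2 + dy^2)
    if (mag < params$min_displacement / 60) {
      discards <- rbind(discards, discard_row("saccade", rec$t[on], rec$t[off],
                                              "below_min_displacement"))
      next
    }
    sp <- sqrt(vel$vx[on:off]^2 + vel$vy[on:off]^2)
    rows[[k]] <- data.frame(
      onset_idx = on, offset_idx = off,
      onset_t = rec$t[on], offset_t = rec$t[off],
      dx = dx, dy = dy, magnitude = mag,
      direction = direction_deg(dx, dy),
      peak_speed = if (all(is.na(sp))) NA_real_ else max(sp, na.rm = TRUE))
  }
  saccades <- do.call(rbind, c(list(empty), rows[!vapply(rows, is.null,
                                                         logical(1))]))
  rownames(saccades) <- NULL
  list(saccades = saccades, discards = discards)
}

#' Code inter-saccadic intervals as drift episodes
#'
#' The complement of the detected saccades within the segment — including
#' the stretches before the first and after the last saccade — is coded as
#' drift, except that any interval containing an invalid sample is
#' discarded whole and intervals not strictly longer than
#' `min_drift_duration` are dropped.
#'
#' @param segment A `gaze_segment` or [gaze_recording()].
#' @param saccades Saccade data frame from [finalize_saccades()].
#' @param params A [detection_params()].
#' @return Data frame with `start_idx`, `end_idx` (inclusive), `start_t`,
#'   `end_t`, `duration` (s).
#' @export
segment_drift <- function(segment, saccades, params = detection_params()) {
  rec <- as_gaze_recording(segment)
  n <- length(rec$t)
  bounds <- if (nrow(saccades) == 0) cbind(1L, n) else {
    starts <- c(1L, saccades$offset_idx + 1L)
    ends <- c(saccades$onset_idx - 1L, n)
    cbind(starts, ends)
  }
  rows <- lapply(seq_len(nrow(bounds)), function(i) {
    s <- bounds[i, 1]; e <- bounds[i, 2]
    if (s > e) return(NULL)
    if (!all(rec$valid[s:e])) return(NULL)
    dur <- rec$t[e] - rec$t[s]
    if (dur <= params$min_drift_duration) return(NULL)
    data.frame(start_idx = s, end_idx = e,
               start_t = rec$t[s], end_t = rec$t[e], duration = dur)
  })
  out <- do.call(rbind, c(list(drift_frame()),
                          rows[!vapply(rows, is.null, logical(1))]))
  rownames(out) <- NULL
  out
}

#' Apply warm-up and eccentricity exclusion rules
#'
#' Removes saccades with onset during the segment's first half second
#' (warm-up, to skip target-acquiring saccades after the mask interval) or
#' whose pre-onset or post-offset position lies further than
#' `exclusion_radius` from the target center; removes drift episodes
#' starting during the warm-up or whose mean position (over valid samples)
#' exceeds the radius. Exclusions are counted per rule, never silently
#' dropped.
#'
#' @param saccades,drifts Event data frames from [finalize_saccades()] and
#'   [segment_drift()].
#' @param segment A `gaze_segment` or [gaze_recording()]; the warm-up is
#'   measured from its first timestamp.
#' @param center Target center `c(x, y)` in degrees (default from the
#'   segment, else the origin).
#' @param params A [detection_params()].
#' @return A list with filtered `saccades`, `drifts` and a named integer
#'   `exclusion_counts`.
#' @export
apply_exclusions <- function(saccades, drifts, segment, center = NULL,
                             params = detection_params()) {
  rec <- as_gaze_recording(segment)
  if (is.null(center))
    center <- if (inherits(segment, "gaze_segment")) segment$center else c(0, 0)
  t0 <- rec$t[1]
  counts <- c(saccade_warmup = 0L, saccade_distance = 0L,
              drift_warmup = 0L, drift_distance = 0L)
  keep_s <- rep(TRUE, nrow(saccades))
  for (k in seq_len(nrow(saccades))) {
    if (saccades$onset_t[k] - t0 < params$warmup) {
      keep_s[k] <- FALSE; counts["saccade_warmup"] <- counts["saccade_warmup"] + 1L
      next
    }
    pre <- saccades$onset_idx[k] - 1L
    post <- saccades$offset_idx[k] + 1L
    d_pre <- sqrt((rec$x[pre] - center[1])^2 + (rec$y[pre] - center[2])^2)
    d_post <- sqrt((rec$x[post] - center[1])^2 + (rec$y[post] - center[2])^2)
    if (d_pre > params$exclusion_radius || d_post > params$exclusion_radius) {
      keep_s[k] <- FALSE
      counts["saccade_distance"] <- counts["saccade_distance"] + 1L
    }
  }
  keep_d <- rep(TRUE, nrow(drifts))
  for (k in seq_len(nrow(drifts))) {
    if (drifts$start_t[k] - t0 < params$warmup) {
      keep_d[k] <- FALSE; counts["drift_warmup"] <- counts["drift_warmup"] + 1L
      next
    }
    idx <- drifts$start_idx[k]:drifts$end_idx[k]
    idx <- idx[rec$valid[idx]]
    mx <- mean(rec$x[idx]); my <- mean(rec$y[idx])
    if (sqrt((mx - center[1])^2 + (my - center[2])^2) >
        params$exclusion_radius) {
      keep_d[k] <- FALSE
      counts["drift_distance"] <- counts["drift_distance"] + 1L
    }
  }
  list(saccades = saccades[keep_s, , drop = FALSE],
       drifts = drifts[keep_d, , drop = FALSE],
       exclusion_counts = counts)
}

#' Detect fixational events in a segment
#'
#' Runs the full detection chain: smoothed velocity, median-based elliptic
#' thresholds, supra-threshold candidate runs, 20-ms merging, displacement
#' filtering, drift-episode coding and the warm-up/eccentricity exclusion
#' rules.
#'
#' @param segment A `gaze_segment` or [gaze_recording()].
#' @param params A [detection_params()].
#' @param center Target center; see [apply_exclusions()].
#' @param exclude Apply the exclusion rules (default `TRUE`).
#' @return An object of class `fem_events`: a list with `saccades`,
#'   `drifts`, `discards`, `exclusion_counts`, `thresholds`, `params` and
#'   the analysed `segment`.
#' @export
#' @examples
#' sim <- simulate_session(simulation_config(duration = 5, seed = 7))
#' ev <- detect_events(sim$recording)
#' ev
detect_events <- function(segment, params = detection_params(),
                          center = NULL, exclude = TRUE) {
  vel <- compute_velocity(segment, params)
  thr <- estimate_thresholds(vel, params$lambda_thresh)
  cand <- detect_candidates(vel, thr, params)
  rec <- as_gaze_recording(segment)
  merged <- merge_candidates(cand, rec$t, params$merge_gap)
  fin <- finalize_saccades(segment, merged, params, vel)
  drifts <- segment_drift(segment, fin$saccades, params)
  if (exclude) {
    exc <- apply_exclusions(fin$saccades, drifts, segment, center, params)
    saccades <- exc$saccades; drifts <- exc$drifts
    counts <- exc$exclusion_counts
  } else {
    saccades <- fin$saccades
    counts <- c(saccade_warmup = 0L, saccade_distance = 0L,
                drift_warmup = 0L, drift_distance = 0L)
  }
  rownames(saccades) <- rownames(drifts) <- NULL
  structure(list(saccades = saccades, drifts = drifts,
                 discards = fin$discards, exclusion_counts = counts,
                 thresholds = thr, params = params, segment = segment),
            class = "fem_events")
}

#' @export
print.fem_events <- function(x, ...) {
  cat(sprintf("Fixational events: %d microsaccades, %d drift episodes\n",
              nrow(x$saccades), nrow(x$drifts)))
  cat(sprintf("  thresholds eta = (%.3g, %.3g) deg/s; %d candidate(s) discarded, %d excluded\n",
              x$thresholds$eta_x, x$thresholds$eta_y,
              nrow(x$discards), sum(x$exclusion_counts)))
  invisible(x)
}

#' @export
summary.fem_events <- function(object, ...) {
  s <- object$saccades; d <- object$drifts
  cat(sprintf("Microsaccades: n = %d", nrow(s)))
  if (nrow(s) > 0)
    cat(sprintf(", median magnitude %.3f deg, median peak speed %.2f deg/s",
                stats::median(s$magnitude), stats::median(s$peak_speed)))
  cat("\n")
  cat(sprintf("Drift episodes: n = %d", nrow(d)))
  if (nrow(d) > 0)
    cat(sprintf(", median duration %.0f ms", 1000 * stats::median(d$duration)))
  cat("\n")
  cat("Exclusions:", paste(names(object$exclusion_counts),
                           object$exclusion_counts, collapse = ", "), "\n")
  invisible(object)
}

#' Plot detected events over the gaze trace
#'
#' @param x An `fem_events` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fem_events <- function(x, ...) {
  rec <- as_gaze_recording(x$segment)
  graphics::matplot(rec$t, cbind(rec$x, rec$y), type = "l", lty = 1,
                    col = c("black", "grey50"),
                    xlab = "time (s)", ylab = "gaze (deg)", ...)
  if (nrow(x$saccades) > 0) {
    graphics::points(x$saccades$onset_t, rec$x[x$saccades$onset_idx],
                     col = "blue", pch = 16, cex = 0.6)
    graphics::points(x$saccades$offset_t, rec$x[x$saccades$offset_idx],
                     col = "red", pch = 16, cex = 0.6)
  }
  graphics::legend("topright", legend = c("x", "y", "onset", "offset"),
                   col = c("black", "grey50", "blue", "red"),
                   lty = c(1, 1, NA, NA), pch = c(NA, NA, 16, 16), bty = "n")
  invisible(x)
}

# direction of a displacement vector, degrees in [0, 360), +y up, 0 = rightward
direction_deg <- function(dx, dy) {
  d <- atan2(dy, dx) * 180 / pi
  (d + 360) %% 360
}

saccade_frame <- function() data.frame(
  onset_idx = integer(), offset_idx = integer(),
  onset_t = numeric(), offset_t = numeric(),
  dx = numeric(), dy = numeric(), magnitude = numeric(),
  direction = numeric(), peak_speed = numeric())

drift_frame <- function() data.frame(
  start_idx = integer(), end_idx = integer(),
  start_t = numeric(), end_t = numeric(), duration = numeric())

discard_frame <- function() data.frame(
  type = character(), onset_t = numeric(), offset_t = numeric(),
  reason = character())

discard_row <- function(type, on, off, reason)
  data.frame(type = type, onset_t = on, offset_t = off, reason = reason)
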