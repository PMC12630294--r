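# Shared fixtures and an independent brute-force implementation of the
# velocity-threshold detector, used as the oracle for equivalence tests.

HZ <- 620

# a recording with constant sampling and given positions
make_recording <- function(x, y = rep(0, length(x)), valid = NULL,
                           rate = HZ) {
  gaze_recording(t = (seq_along(x) - 1) / rate, x = x, y = y,
                 valid = valid, nominal_rate = rate)
}

# quiet drift-like random walk with injected instantaneous steps
make_stepped_recording <- function(n = 1200, steps = list(), noise_sd = 0,
                                   rate = HZ, seed = 1) {
  set.seed(seed)
  x <- cumsum(rnorm(n, 0, 1e-4))
  y <- cumsum(rnorm(n, 0, 1e-4))
  for (s in steps) {   # s: list(at = sample index, dx, dy)
    x[s$at:n] <- x[s$at:n] + s$dx
    y[s$at:n] <- y[s$at:n] + s$dy
  }
  if (noise_sd > 0) {
    x <- x + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
  }
  make_recording(x, y, rate = rate)
}

# ---- independent brute-force detector ------------------------------------
# Direct per-sample criterion scan plus naive merging; shares no code with
# the package implementation.

brute_velocity <- function(rec, params) {
  n <- length(rec$t)
  dt <- median(diff(rec$t))
  half <- (params$velocity_window - 1) / 2
  denom <- 2 * sum(seq_len(half)) * dt
  vx <- vy <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - half; hi <- i + half
    if (lo >= 1 && hi <= n && all(rec$valid[lo:hi])) {
      sx <- 0; sy <- 0
      for (k in seq_len(half)) {
        sx <- sx + rec$x[i + k] - rec$x[i - k]
        sy <- sy + rec$y[i + k] - rec$y[i - k]
      }
      vx[i] <- sx / denom; vy[i] <- sy / denom
    }
  }
  list(vx = vx, vy = vy)
}

brute_detect <- function(rec, params = detection_params()) {
  v <- brute_velocity(rec, params)
  med <- function(z) median(z, na.rm = TRUE)
  sx <- sqrt(med(v$vx^2) - med(v$vx)^2)
  sy <- sqrt(med(v$vy^2) - med(v$vy)^2)
  ex <- params$lambda_thresh * sx; ey <- params$lambda_thresh * sy
  above <- (v$vx / ex)^2 + (v$vy / ey)^2 > 1
  above[is.na(above)] <- FALSE
  n <- length(above)
  runs <- list(); start <- NA
  for (i in seq_len(n)) {
    if (above[i] && is.na(start)) start <- i
    if (!is.na(start) && (!above[i] || i == n)) {
      end <- if (above[i]) i else i - 1L
      if (end - start + 1L >= params$min_duration)
        runs[[length(runs) + 1L]] <- c(start, end)
      start <- NA
    }
  }
  # naive merging: repeatedly join the first pair closer than the gap
  changed <- TRUE
  while (changed && length(runs) > 1) {
    changed <- FALSE
    for (j in seq_len(length(runs) - 1)) {
      if (rec$t[runs[[j + 1]][1]] - rec$t[runs[[j]][2]] < params$merge_gap) {
        runs[[j]] <- c(runs[[j]][1], runs[[j + 1]][2])
        runs[[j + 1]] <- NULL
        changed <- TRUE
        break
      }
    }
  }
  # displacement filter on flanking samples
  keep <- list()
  for (r in runs) {
    pre <- r[1] - 1L; post <- r[2] + 1L
    if (pre < 1L || post > n || !rec$valid[pre] || !rec$valid[post]) next
    mag <- sqrt((rec$x[post] - rec$x[pre])^2 + (rec$y[post] - rec$y[pre])^2)
    if (mag >= params$min_displacement / 60)
      keep[[length(keep) + 1L]] <- r
  }
  if (length(keep) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("onset", "offset"))))
  out <- do.call(rbind, keep)
  colnames(out) <- c("onset", "offset")
  out
}

# detection without the warm-up/eccentricity exclusions, as interval matrix
package_detect_intervals <- function(rec, params = detection_params()) {
  ev <- detect_events(rec, params, exclude = FALSE)
  cbind(onset = ev$saccades$onset_idx, offset = ev$saccades$offset_idx)
}
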