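#' Configuration for the synthetic gaze generator
#'
#' Defines a simulated fixation session: slow ocular drift, microsaccades
#' at a dead-time-thinned Poisson rate with lognormal amplitudes and uni-
#' or bimodal (opposed von Mises) directions, optional square-wave-jerk
#' (SWJ) pairing, additive sensor noise calibrated to a target RMS-S2S,
#' and occasional data-loss episodes. The defaults emulate the empirical
#' regime of 30-s fixation trials recorded with a high-precision retinal
#' tracker: drift at 0.76 deg/s mean speed with a predominant rightward
#' direction, microsaccades at ~1.8 Hz with ~0.1-0.4 deg displacements in
#' two opposed horizontal modes (the predominant drift direction opposite
#' one of them), sensor noise of 0.156 arcmin RMS-S2S and ~0.65% data loss.
#'
#' @param duration Trial duration in seconds (default 30).
#' @param rate Nominal sampling rate in Hz (default 620).
#' @param drift_mode `"directed"` (constant step length, von Mises heading
#'   random walk with weak pull toward the bias direction) or
#'   `"diffusion"` (2D Brownian steps of matching expected speed).
#' @param drift_speed Target mean drift speed in deg/s (default 0.76).
#' @param drift_direction_bias Predominant drift direction in degrees
#'   (default 0, rightward).
#' @param drift_concentration von Mises concentration of per-sample heading
#'   innovations (default 10); `Inf` gives a straight-line path.
#' @param saccade_rate Poisson rate of microsaccades in Hz before dead-time
#'   thinning (default 1.8).
#' @param refractory Dead time between saccades in seconds (default 0.15).
#' @param amplitude_median,amplitude_log_sd Lognormal saccade amplitude
#'   distribution: median in degrees (default 0.22) and SD on the log scale
#'   (default 0.35).
#' @param amplitude_min Optional floor (deg) on the net injected saccade
#'   displacement (default 0, no floor).
#' @param direction_modes One or two saccade direction modes in degrees
#'   (default `c(180, 0)`: leftward/rightward, opposed).
#' @param direction_weights Mode weights (default `c(0.6, 0.4)`).
#' @param direction_concentration von Mises concentration within a mode
#'   (default 8).
#' @param swj_fraction Fraction of saccades paired as SWJs with an opposed
#'   return saccade (default 0.3).
#' @param swj_return_latency Latency of the SWJ return saccade in seconds
#'   (default 0.2).
#' @param recentering_gain Fraction of the current gaze offset corrected by
#'   each non-SWJ saccade (default 0.85); values near 1 keep 30-s traces
#'   well within the 2.5 deg exclusion radius.
#' @param noise_rms_s2s Target sensor-noise RMS-S2S in arcmin (default
#'   0.156); per-axis noise SD is half this value.
#' @param loss_rate Rate of data-loss episodes in Hz (default 0.065).
#' @param loss_duration Duration of each loss episode in seconds (default
#'   0.1); defaults give ~0.65% expected loss.
#' @param n_trials Number of consecutive pseudo-trials to emit in the
#'   manifest (default 1; use 5 for a full session).
#' @param seed Integer seed; every source of randomness in the generator
#'   flows from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(duration = 30, rate = 620,
                              drift_mode = c("directed", "diffusion"),
                              drift_speed = 0.76, drift_direction_bias = 0,
                              drift_concentration = 10,
                              saccade_rate = 1.8, refractory = 0.15,
                              amplitude_median = 0.22, amplitude_log_sd = 0.35,
                              amplitude_min = 0,
                              direction_modes = c(180, 0),
                              direction_weights = c(0.6, 0.4),
                              direction_concentration = 8,
                              swj_fraction = 0.3, swj_return_latency = 0.2,
                              recentering_gain = 0.85,
                              noise_rms_s2s = 0.156,
                              loss_rate = 0.065, loss_duration = 0.1,
                              n_trials = 1, seed = 1) {
  drift_mode <- match.arg(drift_mode)
  cfg <- as.list(environment())
  if (duration <= 0 || rate <= 0 || refractory < 0)
    stop_fem_config("durations and rates must be positive")
  if (saccade_rate < 0 || saccade_rate * refractory >= 1)
    stop_fem_config("infeasible saccade rate/refractory combination")
  if (swj_fraction < 0 || swj_fraction > 1)
    stop_fem_config("swj_fraction must lie in [0, 1]")
  if (recentering_gain < 0 || recentering_gain > 1)
    stop_fem_config("recentering_gain must lie in [0, 1]")
  if (noise_rms_s2s < 0 || loss_rate < 0 || loss_duration < 0)
    stop_fem_config("noise and loss parameters must be nonnegative")
  if (length(direction_modes) != length(direction_weights))
    stop_fem_config("direction_modes and direction_weights must match")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation: %d x %g s at %g Hz, seed %d\n",
              x$n_trials, x$duration, x$rate, x$seed))
  cat(sprintf("  drift %s %.3g deg/s; saccades %.3g Hz, median %.3g deg, SWJ %.0f%%\n",
              x$drift_mode, x$drift_speed, x$saccade_rate,
              x$amplitude_median, 100 * x$swj_fraction))
  cat(sprintf("  noise %.3g arcmin RMS-S2S; loss %.3g Hz x %.3g s\n",
              x$noise_rms_s2s, x$loss_rate, x$loss_duration))
  invisible(x)
}

#' von Mises random deviates
#'
#' Best-Fisher rejection sampler for circular deviates with mean `mu`
#' (radians) and concentration `kappa`; `kappa = 0` gives the uniform
#' circle, large `kappa` approaches a wrapped normal of variance
#' `1/kappa`.
#'
#' @param n Number of deviates.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0).
#' @return Numeric vector of angles in radians (unwrapped around `mu`).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(mu + stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.3 * (n - length(out))))
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    sgn <- sign(stats::runif(m) - 0.5)
    out <- c(out, (sgn * acos(f))[ok])
  }
  mu + out[seq_len(n)]
}

#' Simulate a noise-free drift path
#'
#' Directed mode: every inter-sample step has length `drift_speed / rate`
#' (so the realized mean step speed equals the target exactly), with the
#' heading following a von Mises random walk that is weakly pulled toward
#' `drift_direction_bias`. Diffusion mode: i.i.d. 2D Gaussian steps whose
#' expected length matches the target speed.
#'
#' @param config A [simulation_config()].
#' @param n_samples Number of samples (default `duration * rate * n_trials`).
#' @param seed Seed (default from the config).
#' @return A list with `t`, `x`, `y` (deg), starting at the origin.
#' @export
simulate_drift <- function(config, n_samples = NULL, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(n_samples))
    n_samples <- round(config$duration * config$rate * config$n_trials)
  local_seed(seed)
  n_steps <- n_samples - 1L
  L <- config$drift_speed / config$rate
  if (config$drift_mode == "directed") {
    innov <- rvonmises(n_steps, 0, config$drift_concentration)
    bias <- config$drift_direction_bias * pi / 180
    theta <- numeric(n_steps)
    h <- bias
    pull <- 0.02   # per-sample heading relaxation toward the bias direction
    for (k in seq_len(n_steps)) {
      h <- h + innov[k] + pull * wrap_angle(bias - h)
      theta[k] <- h
    }
    dx <- L * cos(theta); dy <- L * sin(theta)
  } else {
    s <- L / sqrt(pi / 2)   # Rayleigh mean sigma*sqrt(pi/2) = L
    dx <- stats::rnorm(n_steps, 0, s); dy <- stats::rnorm(n_steps, 0, s)
  }
  list(t = (seq_len(n_samples) - 1L) / config$rate,
       x = c(0, cumsum(dx)), y = c(0, cumsum(dy)))
}

#' Sample saccade onset times
#'
#' Homogeneous Poisson arrivals at `saccade_rate`, thinned by the
#' refractory dead time: an arrival closer than `refractory` to the
#' previously accepted one is dropped, so the realized rate is
#' approximately `rate / (1 + rate * refractory)`.
#'
#' @param config A [simulation_config()].
#' @param total_duration Seconds to cover (default
#'   `duration * n_trials`).
#' @param seed Seed (default from the config).
#' @return Increasing numeric vector of onset times in seconds.
#' @export
sample_saccade_times <- function(config, total_duration = NULL,
                                 seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(total_duration))
    total_duration <- config$duration * config$n_trials
  if (config$saccade_rate == 0) return(numeric(0))
  local_seed(seed)
  expected <- config$saccade_rate * total_duration
  gaps <- stats::rexp(ceiling(expected + 6 * sqrt(expected) + 10),
                      config$saccade_rate)
  arrivals <- cumsum(gaps)
  while (sum(gaps) < total_duration) {
    gaps <- c(gaps, stats::rexp(100, config$saccade_rate))
    arrivals <- cumsum(gaps)
  }
  arrivals <- arrivals[arrivals < total_duration]
  out <- numeric(0); last <- -Inf
  for (a in arrivals) {
    if (a - last >= config$refractory) {
      out <- c(out, a); last <- a
    }
  }
  out
}

#' Saccade position waveform
#'
#' Raised-cosine position profile with a linear main-sequence duration
#' rule: `duration = max(6 ms, 21 ms + 2.2 ms/deg * amplitude)`. The net
#' displacement equals the requested amplitude in the requested direction
#' exactly; the peak speed always exceeds `amplitude / duration`.
#'
#' @param amplitude Saccade amplitude in degrees (> 0).
#' @param direction Direction in degrees (0 = rightward, 90 = upward).
#' @param sr Sampling rate in Hz.
#' @return A two-column matrix of cumulative (dx, dy) sample displacements
#'   relative to the pre-saccade position; one row per sample of the
#'   saccade.
#' @export
saccade_waveform <- function(amplitude, direction, sr) {
  if (amplitude <= 0) stop_fem_config("amplitude must be positive")
  dur <- max(0.006, 0.021 + 0.0022 * amplitude)
  m <- max(2L, as.integer(round(dur * sr)))
  u <- seq_len(m) / m
  prof <- amplitude * (1 - cos(pi * u)) / 2
  th <- direction * pi / 180
  cbind(dx = prof * cos(th), dy = prof * sin(th))
}

#' Add calibrated sensor noise
#'
#' Adds i.i.d. Gaussian noise with per-axis SD equal to half the target
#' RMS-S2S (converted arcmin to degrees), so that the measured RMS-S2S of
#' a static trace matches the target: for independent noise,
#' E\[dx^2 + dy^2\] = 4 sigma^2 across a sample-to-sample step.
#'
#' @param recording A [gaze_recording()].
#' @param noise_rms_s2s Target RMS-S2S in arcmin (>= 0).
#' @param seed Optional seed.
#' @return The noisy recording.
#' @export
add_noise <- function(recording, noise_rms_s2s, seed = NULL) {
  stopifnot(inherits(recording, "gaze_recording"))
  if (noise_rms_s2s < 0) stop_fem_config("noise_rms_s2s must be >= 0")
  if (noise_rms_s2s == 0) return(recording)
  if (!is.null(seed)) local_seed(seed)
  s <- (noise_rms_s2s / 2) / 60
  n <- length(recording$t)
  recording$x <- recording$x + stats::rnorm(n, 0, s)
  recording$y <- recording$y + stats::rnorm(n, 0, s)
  recording
}

#' Simulate a full fixation session with ground truth
#'
#' Composes drift, microsaccades (with recentering and optional SWJ
#' pairing), sensor noise and data loss into a gaze recording, together
#' with a matching trial manifest and the ground truth of every injected
#' event. Fully reproducible from the seed.
#'
#' Saccade composition: each non-SWJ saccade's displacement is the sampled
#' amplitude vector minus `recentering_gain` times the current gaze offset,
#' which keeps long traces centered; an SWJ pair is an uncorrected saccade
#' followed after `swj_return_latency` by an equal, opposed return. Ground
#' truth records the realized (net) displacement of every injected saccade.
#'
#' @param config A [simulation_config()].
#' @param seed Seed (default from the config).
#' @return A list of class `fem_simulation` with `recording`
#'   ([gaze_recording()]), `ground_truth` (list: `saccades` data frame with
#'   `onset_idx`, `offset_idx`, `onset_t`, `offset_t`, `dx`, `dy`,
#'   `amplitude`, `direction`, `is_swj`; `drift` noise-free path;
#'   `loss` intervals) and `manifest` ([trial_manifest()]).
#' @export
simulate_session <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  local_seed(seed)
  rate <- config$rate
  total_dur <- config$duration * config$n_trials
  n <- round(total_dur * rate)
  t <- (seq_len(n) - 1L) / rate

  drift <- simulate_drift(config, n_samples = n, seed = NULL)
  x <- drift$x; y <- drift$y

  onsets_t <- sample_saccade_times(config, total_dur, seed = NULL)
  queue <- data.frame(t = onsets_t,
                      is_swj_return = rep(FALSE, length(onsets_t)),
                      ret_dx = rep(NA_real_, length(onsets_t)),
                      ret_dy = rep(NA_real_, length(onsets_t)))
  gt_rows <- list()
  last_end <- 0L
  qi <- 1L
  while (qi <= nrow(queue)) {
    ev <- queue[qi, ]; qi <- qi + 1L
    i0 <- as.integer(floor(ev$t * rate)) + 1L
    if (i0 <= last_end + 1L) next          # overlaps the previous event
    if (ev$is_swj_return) {
      d <- c(ev$ret_dx, ev$ret_dy)
      is_swj <- TRUE
    } else {
      is_swj <- stats::runif(1) < config$swj_fraction
      d <- sample_saccade_vector(config)
      if (!is_swj) {
        cur <- c(x[i0], y[i0])   # previous saccades already folded into x, y
        d <- d - config$recentering_gain * cur
        tries <- 0L
        while (config$amplitude_min > 0 &&
               sqrt(sum(d^2)) < config$amplitude_min && tries < 100L) {
          d <- sample_saccade_vector(config) -
            config$recentering_gain * cur
          tries <- tries + 1L
        }
        if (config$amplitude_min > 0 && sqrt(sum(d^2)) < config$amplitude_min)
          d <- d * config$amplitude_min / max(sqrt(sum(d^2)), 1e-12)
      }
    }
    amp <- sqrt(sum(d^2))
    if (amp <= 0) next
    wf <- saccade_waveform(amp, direction_deg(d[1], d[2]), rate)
    m <- nrow(wf)
    if (i0 + m - 1L > n - 1L) next         # would run past the recording
    idx <- i0:(i0 + m - 1L)
    x[idx] <- x[idx] + wf[, 1]
    y[idx] <- y[idx] + wf[, 2]
    if (idx[length(idx)] < n) {
      rest <- (idx[length(idx)] + 1L):n
      x[rest] <- x[rest] + d[1]
      y[rest] <- y[rest] + d[2]
    }
    gt_rows[[length(gt_rows) + 1L]] <- data.frame(
      onset_idx = i0, offset_idx = idx[length(idx)],
      onset_t = t[i0], offset_t = t[idx[length(idx)]],
      dx = d[1], dy = d[2], amplitude = amp,
      direction = direction_deg(d[1], d[2]), is_swj = is_swj)
    last_end <- idx[length(idx)]
    if (is_swj && !ev$is_swj_return) {
      ret_t <- t[idx[length(idx)]] + config$swj_return_latency
      if (ret_t < total_dur) {
        ins <- data.frame(t = ret_t, is_swj_return = TRUE,
                          ret_dx = -d[1], ret_dy = -d[2])
        later <- queue$t > ret_t & seq_len(nrow(queue)) >= qi
        queue <- rbind(queue[seq_len(qi - 1L), , drop = FALSE], ins,
                       queue[later, , drop = FALSE])
      }
    }
  }
  gt_sacc <- do.call(rbind, c(list(data.frame(
    onset_idx = integer(), offset_idx = integer(), onset_t = numeric(),
    offset_t = numeric(), dx = numeric(), dy = numeric(),
    amplitude = numeric(), direction = numeric(), is_swj = logical())),
    gt_rows))

  clean <- list(x = x, y = y)
  rec <- gaze_recording(t, x, y, nominal_rate = rate)
  rec <- add_noise(rec, config$noise_rms_s2s)

  loss <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("t_start", "t_end")))
  if (config$loss_rate > 0 && config$loss_duration > 0) {
    n_loss <- stats::rpois(1, config$loss_rate * total_dur)
    if (n_loss > 0) {
      starts <- sort(stats::runif(n_loss, 0, total_dur - config$loss_duration))
      loss <- cbind(t_start = starts, t_end = starts + config$loss_duration)
      for (k in seq_len(n_loss)) {
        sel <- t >= loss[k, 1] & t < loss[k, 2]
        rec$x[sel] <- NA_real_; rec$y[sel] <- NA_real_
        rec$valid[sel] <- FALSE
      }
    }
  }

  labels <- rep_len(c("Gaussian", "Bessel", "Circle", "Point", "CCP"),
                    config$n_trials)
  manifest <- trial_manifest(
    data.frame(label = labels, polarity = "white-on-black",
               t_on = (seq_len(config$n_trials) - 1) * config$duration,
               t_off = seq_len(config$n_trials) * config$duration,
               cx = 0, cy = 0),
    trial_duration = config$duration)

  structure(list(recording = rec,
                 ground_truth = list(saccades = gt_sacc,
                                     drift = drift,
                                     clean = clean,
                                     loss = loss),
                 manifest = manifest, config = config),
            class = "fem_simulation")
}

#' @export
print.fem_simulation <- function(x, ...) {
  cat(sprintf("Simulated session: %d samples, %d injected saccades (%d SWJ), %.2f%% loss\n",
              length(x$recording$t), nrow(x$ground_truth$saccades),
              sum(x$ground_truth$saccades$is_swj),
              100 * data_loss_fraction(x$recording)))
  invisible(x)
}

# one sampled amplitude vector (before recentering)
sample_saccade_vector <- function(config) {
  a <- stats::rlnorm(1, log(config$amplitude_median), config$amplitude_log_sd)
  mode <- sample.int(length(config$direction_modes), 1,
                     prob = config$direction_weights)
  th <- rvonmises(1, config$direction_modes[mode] * pi / 180,
                  config$direction_concentration)
  c(a * cos(th), a * sin(th))
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

# seed the generator RNG; NULL continues the current stream (nested calls)
local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible()
}
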