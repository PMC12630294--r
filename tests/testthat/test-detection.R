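test_that("smoothed velocity matches the window-5 stencil", {
  p <- detection_params()

  # constant position: zero velocity wherever defined
  v <- compute_velocity(make_recording(rep(0.5, 50), rep(-0.5, 50)), p)
  expect_true(all(abs(v$vx[v$defined]) < 1e-12))
  expect_true(all(abs(v$vy[v$defined]) < 1e-12))
  expect_false(any(v$defined[c(1, 2, 49, 50)]))  # stencil edges undefined

  # linear ramp x = s*t: stencil exact at interior samples
  s <- 3.7
  t <- (0:49) / HZ
  v <- compute_velocity(make_recording(s * t, rep(0, 50)), p)
  expect_equal(v$vx[v$defined], rep(s, sum(v$defined)), tolerance = 1e-9)

  # direct stencil evaluation: x = [0,0,0,1,1,1] deg at 620 Hz
  v <- compute_velocity(make_recording(c(0, 0, 0, 1, 1, 1), rep(0, 6)), p)
  expect_equal(v$vx[3], (1 + 1 - 0 - 0) / (6 / HZ))  # 620/3 deg/s
  expect_equal(v$vx[4], 620 / 3)

  # velocities adjacent to an invalid sample are undefined, not interpolated
  val <- rep(TRUE, 50); val[25] <- FALSE
  v <- compute_velocity(make_recording(rep(0, 50), rep(0, 50), valid = val), p)
  expect_false(any(v$defined[23:27]))
  expect_true(v$defined[22] && v$defined[28])

  expect_error(compute_velocity(make_recording(c(0, 0, 0), rep(0, 3)), p),
               class = "fem_data_error")
})

test_that("median-based thresholds follow the noise estimator", {
  fake_vel <- function(vx, vy = vx) {
    structure(list(vx = vx, vy = vy, defined = rep(TRUE, length(vx)),
                   dt = 1 / HZ), class = "velocity_series")
  }
  # hand evaluation: vx = [-2,-1,0,1,2] tiled -> median 0, median(v^2) = 1
  v <- fake_vel(rep(c(-2, -1, 0, 1, 2), 4))
  thr <- estimate_thresholds(v, lambda_thresh = 6)
  expect_equal(thr$sigma_x, 1)
  expect_equal(thr$eta_x, 6)

  # all velocities equal: degenerate signal
  expect_error(estimate_thresholds(fake_vel(rep(1, 20))),
               class = "fem_data_error")

  # Gaussian velocities with true SD s: sigma -> sqrt(median chi2_1) * s
  set.seed(5)
  s <- 2.5
  thr <- estimate_thresholds(fake_vel(rnorm(1e5, 0, s), rnorm(1e5, 0, s)), 6)
  expect_equal(thr$sigma_x, 0.6745 * s, tolerance = 0.01)
  expect_equal(thr$sigma_y, 0.6745 * s, tolerance = 0.01)
})

test_that("candidate runs obey the elliptic criterion and minimum duration", {
  p <- detection_params()
  mk_vel <- function(vx, vy = rep(0, length(vx)), defined = rep(TRUE, length(vx))) {
    structure(list(vx = vx, vy = vy, defined = defined, dt = 1 / HZ),
              class = "velocity_series")
  }
  thr <- structure(list(sigma_x = 1, sigma_y = 1, eta_x = 6, eta_y = 6),
                   class = "ek_thresholds")

  # all sub-threshold
  expect_equal(nrow(detect_candidates(mk_vel(rep(1, 30)), thr, p)), 0)

  # a 2-sample supra-threshold run is shorter than min_duration 3
  vx <- rep(0, 30); vx[10:11] <- 10
  expect_equal(nrow(detect_candidates(mk_vel(vx), thr, p)), 0)

  # a 5-sample run embedded in quiet signal: exactly that interval
  vx <- rep(0, 30); vx[12:16] <- 10
  out <- detect_candidates(mk_vel(vx), thr, p)
  expect_equal(unname(out), cbind(12L, 16L))

  # the criterion is elliptic: both axes at eta/sqrt(2) exceeds threshold
  vx <- rep(0, 30); vy <- rep(0, 30)
  vx[5:9] <- 6 / sqrt(2) * 1.01; vy[5:9] <- 6 / sqrt(2) * 1.01
  expect_equal(nrow(detect_candidates(mk_vel(vx, vy), thr, p)), 1)

  # runs may not span undefined samples
  vx <- rep(0, 30); vx[10:16] <- 10
  def <- rep(TRUE, 30); def[13] <- FALSE
  out <- detect_candidates(mk_vel(vx, defined = def), thr, p)
  expect_equal(unname(out), cbind(c(10L, 14L), c(12L, 16L)))
})

test_that("merging joins gaps under 20 ms and leaves larger gaps alone", {
  t <- (0:999) / 1000   # 1 kHz for round-millisecond gaps
  # 15-ms gap: merged into one
  iv <- cbind(onset = c(100L, 131L), offset = c(115L, 140L))
  expect_equal(unname(merge_candidates(iv, t, 0.020)), cbind(100L, 140L))
  # 25-ms gap: not merged
  iv <- cbind(onset = c(100L, 141L), offset = c(115L, 150L))
  expect_equal(nrow(merge_candidates(iv, t, 0.020)), 2)
  # single interval unchanged
  iv <- cbind(onset = 100L, offset = 115L)
  expect_equal(merge_candidates(iv, t, 0.020), iv)
  # chained merges reach a fixed point
  iv <- cbind(onset = c(100L, 126L, 152L), offset = c(115L, 141L, 160L))
  expect_equal(unname(merge_candidates(iv, t, 0.020)), cbind(100L, 160L))
})

test_that("finalized saccades carry pre-to-post displacement and respect the 4-arcmin rule", {
  p <- detection_params()
  # injected instantaneous 10-arcmin step
  rec <- make_stepped_recording(steps = list(list(at = 600, dx = 10 / 60, dy = 0)),
                                seed = 21)
  ev <- detect_events(rec, p, exclude = FALSE)
  expect_equal(nrow(ev$saccades), 1)
  expect_equal(ev$saccades$magnitude, 10 / 60, tolerance = 0.05)
  dir_err <- min(ev$saccades$direction, 360 - ev$saccades$direction)
  expect_lt(dir_err, 2)  # rightward, modulo the circle

  # a 3-arcmin step is below the minimum displacement
  rec <- make_stepped_recording(steps = list(list(at = 600, dx = 3 / 60, dy = 0)),
                                seed = 22)
  ev <- detect_events(rec, p, exclude = FALSE)
  expect_equal(nrow(ev$saccades), 0)
  expect_true("below_min_displacement" %in% ev$discards$reason)

  # two opposite 10-arcmin steps 200 ms apart: directions 180 deg apart
  rec <- make_stepped_recording(
    steps = list(list(at = 500, dx = 10 / 60, dy = 0),
                 list(at = 624, dx = -10 / 60, dy = 0)), seed = 23)
  ev <- detect_events(rec, p, exclude = FALSE)
  expect_equal(nrow(ev$saccades), 2)
  dd <- abs(diff(ev$saccades$direction)) %% 360
  expect_equal(min(dd, 360 - dd), 180, tolerance = 3)
})

test_that("drift coding covers loss-free inter-saccadic intervals over 100 ms", {
  p <- detection_params()
  n <- 1240
  rec <- make_recording(rep(0, n), rep(0, n))

  # no saccades, no loss: one episode spanning the whole segment
  d <- segment_drift(rec, data.frame(onset_idx = integer(),
                                     offset_idx = integer()), p)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start_idx, d$end_idx), c(1L, n))

  # one saccade mid-segment: two episodes
  sacc <- data.frame(onset_idx = 600L, offset_idx = 615L)
  d <- segment_drift(rec, sacc, p)
  expect_equal(nrow(d), 2)
  expect_equal(d$start_idx, c(1L, 616L))
  expect_equal(d$end_idx, c(599L, n))

  # an 80-ms inter-saccadic interval is not drift; 120 ms is
  mk_sacc <- function(gap_ms) {
    g <- round(gap_ms / 1000 * HZ)
    data.frame(onset_idx = c(300L, 300L + 15L + g + 1L),
               offset_idx = c(315L, 315L + 15L + g + 1L))
  }
  d80 <- segment_drift(rec, mk_sacc(80), p)
  expect_false(any(d80$start_idx == 316L))
  d120 <- segment_drift(rec, mk_sacc(120), p)
  expect_true(any(d120$start_idx == 316L))

  # an interval containing an invalid sample is discarded whole
  val <- rep(TRUE, n); val[100] <- FALSE
  lossy <- make_recording(rep(0, n), rep(0, n), valid = val)
  d <- segment_drift(lossy, sacc, p)
  expect_equal(d$start_idx, 616L)  # pre-saccade interval dropped entirely
})

test_that("warm-up and eccentricity exclusions fire on the stated rules", {
  p <- detection_params()
  # saccade onset at 0.3 s: discarded by the half-second warm-up
  rec <- make_stepped_recording(n = 1240,
                                steps = list(list(at = 186, dx = 0.2, dy = 0)),
                                seed = 31)
  ev_all <- detect_events(rec, p, exclude = FALSE)
  expect_equal(nrow(ev_all$saccades), 1)
  ev <- detect_events(rec, p)
  expect_equal(nrow(ev$saccades), 0)
  expect_equal(unname(ev$exclusion_counts["saccade_warmup"]), 1L)

  # saccade landing at 2.6 deg eccentricity: discarded by the 2.5 deg rule
  rec <- make_stepped_recording(n = 1240,
                                steps = list(list(at = 600, dx = 2.6, dy = 0)),
                                seed = 32)
  ev <- detect_events(rec, p, center = c(0, 0))
  expect_equal(nrow(ev$saccades), 0)
  expect_equal(unname(ev$exclusion_counts["saccade_distance"]), 1L)
  # same saccade with the target center nearby is retained
  ev2 <- detect_events(rec, p, center = c(2.2, 0))
  expect_equal(nrow(ev2$saccades), 1)

  # a drift episode with mean position ~0.1 deg from center is retained
  # (a mid-segment saccade splits the trace so an episode starts past warm-up)
  ev3 <- detect_events(
    make_stepped_recording(n = 1240,
                           steps = list(list(at = 600, dx = 0.2, dy = 0)),
                           seed = 33),
    p, center = c(0.1, 0))
  expect_gt(nrow(ev3$drifts), 0)
  expect_equal(unname(ev3$exclusion_counts["drift_distance"]), 0L)

  # a drift episode centered 2.6 deg away is excluded by the distance rule
  # (offset base + a mid-segment saccade so an episode starts past warm-up)
  far <- make_stepped_recording(n = 1240,
                                steps = list(list(at = 600, dx = 0.2, dy = 0)),
                                seed = 34)
  far$x <- far$x + 2.6
  ev4 <- detect_events(far, p, center = c(0, 0))
  expect_equal(nrow(ev4$drifts), 0)
  expect_gt(unname(ev4$exclusion_counts["drift_distance"]), 0L)
})

test_that("composed detection equals the brute-force scan on random segments", {
  set.seed(99)
  for (rep_i in 1:12) {
    cfg <- simulation_config(
      duration = 2000 / HZ, saccade_rate = 2.5, refractory = 0.1,
      swj_fraction = 0.4, noise_rms_s2s = 0.3,
      loss_rate = if (rep_i %% 3 == 0) 0.3 else 0,
      seed = 1000 + rep_i)
    sim <- simulate_session(cfg)
    p <- detection_params()
    got <- package_detect_intervals(sim$recording, p)
    want <- brute_detect(sim$recording, p)
    expect_equal(unname(got), unname(want))
  }
})

test_that("the pipeline recovers injected saccades and drift speed", {
  # a small-scale recovery run; the acceptance suite runs the full version
  hits <- 0L; total <- 0L; false_pos <- 0L; time_analyzed <- 0
  for (s in 1:3) {
    cfg <- simulation_config(saccade_rate = 2, noise_rms_s2s = 0.16,
                             amplitude_min = 0.1, seed = 500 + s)
    sim <- simulate_session(cfg)
    ev <- detect_events(sim$recording)
    gt <- sim$ground_truth$saccades
    gt <- gt[gt$onset_t >= cfg$duration - 29.5, ]  # past warm-up
    matched <- vapply(gt$onset_t, function(tt)
      any(abs(ev$saccades$onset_t - tt) <= 0.010), logical(1))
    hits <- hits + sum(matched); total <- total + nrow(gt)
    false_pos <- false_pos + sum(vapply(ev$saccades$onset_t, function(tt)
      !any(abs(gt$onset_t - tt) <= 0.010), logical(1)))
    time_analyzed <- time_analyzed + 29.5
  }
  expect_gte(hits / total, 0.95)
  expect_lte(false_pos / time_analyzed, 0.1)
})

test_that("detection is deterministic and events are disjoint and ordered", {
  cfg <- simulation_config(seed = 77)
  sim <- simulate_session(cfg)
  ev1 <- detect_events(sim$recording)
  ev2 <- detect_events(sim$recording)
  expect_identical(ev1$saccades, ev2$saccades)
  expect_identical(ev1$drifts, ev2$drifts)

  # saccades and drifts mutually disjoint and jointly ordered
  iv <- rbind(cbind(ev1$saccades$onset_idx, ev1$saccades$offset_idx),
              cbind(ev1$drifts$start_idx, ev1$drifts$end_idx))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  expect_true(all(iv[-1, 1] > iv[-nrow(iv), 2]))
  # every drift episode is loss-free and longer than 100 ms
  expect_true(all(ev1$drifts$duration > 0.1))
  for (k in seq_len(nrow(ev1$drifts)))
    expect_true(all(sim$recording$valid[ev1$drifts$start_idx[k]:ev1$drifts$end_idx[k]]))
})
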