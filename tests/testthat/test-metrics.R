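test_that("BCEA matches the closed form and its stated coverage", {
  set.seed(101)
  n <- 1e5
  pts <- cbind(rnorm(n), rnorm(n))
  b <- bcea(pts)
  # isotropic unit variance: area -> 2*pi*(-log(1 - 0.6827))
  expect_equal(b$area, 2 * pi * (-log(1 - 0.6827)), tolerance = 0.02)
  # the ellipse contains the stated fraction of the points
  expect_equal(mean(bcea_contains(b, pts)), 0.6827, tolerance = 0.005)

  # correlated clouds too
  rho <- 0.6
  pts2 <- cbind(pts[, 1], rho * pts[, 1] + sqrt(1 - rho^2) * pts[, 2])
  b2 <- bcea(pts2)
  expect_equal(mean(bcea_contains(b2, pts2)), 0.6827, tolerance = 0.005)

  # degenerate geometry
  expect_error(bcea(cbind(1:10, 2 * (1:10))), class = "fem_data_error")
  expect_error(bcea(cbind(1:2, 1:2)), class = "fem_data_error")
  expect_error(bcea(cbind(1:10, rep(1, 10))), class = "fem_data_error")
})

test_that("BCEA is invariant under translation and rotation", {
  set.seed(102)
  pts <- cbind(rnorm(500, sd = 2), rnorm(500, sd = 0.5))
  a0 <- bcea(pts)$area
  expect_equal(bcea(sweep(pts, 2, c(10, -4)))$area, a0, tolerance = 1e-9)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(bcea(pts %*% R)$area, a0, tolerance = 1e-9)
})

test_that("adding a distant outlier never decreases BCEA area", {
  set.seed(103)
  pts <- cbind(rnorm(300), rnorm(300))
  a0 <- bcea(pts)$area
  for (far in list(c(50, 0), c(0, -50), c(30, 30)))
    expect_gte(bcea(rbind(pts, far))$area, a0)
})

test_that("pooled positions concatenate samples of selected events only", {
  n <- 400
  rec <- make_recording(seq(0, 1, length.out = n), rep(0, n))
  ev <- list(saccades = data.frame(onset_idx = 101L, offset_idx = 110L),
             drifts = data.frame(start_idx = 201L, end_idx = 300L),
             segment = rec)
  pp <- pooled_positions(ev)
  expect_equal(nrow(pp), 110)  # 10 saccade + 100 drift samples
  expect_equal(unname(pp[1, "x"]), rec$x[101])

  # one drift episode of 62 samples, no saccades
  ev2 <- list(saccades = data.frame(onset_idx = integer(),
                                    offset_idx = integer()),
              drifts = data.frame(start_idx = 11L, end_idx = 72L),
              segment = rec)
  expect_equal(nrow(pooled_positions(ev2)), 62)

  # all events excluded -> empty
  ev3 <- list(saccades = ev2$saccades,
              drifts = data.frame(start_idx = integer(), end_idx = integer()),
              segment = rec)
  expect_equal(nrow(pooled_positions(ev3)), 0)

  # invalid samples inside an event are omitted
  val <- rep(TRUE, n); val[205:214] <- FALSE
  recv <- make_recording(rec$x, rec$y, valid = val)
  ev4 <- ev; ev4$segment <- recv
  expect_equal(nrow(pooled_positions(ev4)), 100)
})

test_that("displacement and direction follow the shared convention", {
  expect_equal(displacement_and_direction(c(0, 0), c(1, 0)),
               c(magnitude = 1, direction = 0))
  expect_equal(displacement_and_direction(c(0, 0), c(0, 1)),
               c(magnitude = 1, direction = 90))
  out <- displacement_and_direction(c(0, 0), c(-1, -1))
  expect_equal(unname(out["magnitude"]), sqrt(2), tolerance = 1e-9)
  expect_equal(unname(out["direction"]), 225)
})

test_that("drift path length sums adjacent-sample distances", {
  expect_equal(drift_path_length(c(0, 3), c(0, 4)), 5)
  expect_equal(drift_path_length(c(0, 1, 1), c(0, 0, 1)), 2)  # right-angle zigzag
  # path length >= displacement, on a meandering sample path
  set.seed(104)
  x <- cumsum(rnorm(100, 0, 0.01)); y <- cumsum(rnorm(100, 0, 0.01))
  expect_gte(drift_path_length(x, y),
             sqrt((x[100] - x[1])^2 + (y[100] - y[1])^2))
  expect_error(drift_path_length(1, 1), class = "fem_data_error")
})

test_that("gradient-based drift speed matches closed forms", {
  t <- (0:199) / HZ
  # uniform linear motion: exact (gradient is exact for linear signals)
  expect_equal(drift_speed(0.5 * t, rep(0, 200), t), 0.5)
  expect_equal(drift_speed(0.3 * t, 0.4 * t, t), 0.5)
  # stationary
  expect_equal(drift_speed(rep(1, 200), rep(2, 200), t), 0)
  # circular motion at radius r, angular rate w: speed ~ r*w
  r <- 0.2; w <- 2 * pi
  expect_equal(drift_speed(r * cos(w * t), r * sin(w * t), t), r * w,
               tolerance = 1e-3)
  expect_error(drift_speed(c(0, 1), c(0, 0), c(0, 1)),
               class = "fem_data_error")
})

test_that("saccade rate is count over analysed duration", {
  expect_equal(saccade_rate(59, 29.5), 2)
  expect_equal(saccade_rate(0, 29.5), 0)
  expect_error(saccade_rate(3, 0), class = "fem_data_error")
})

test_that("drift speed of noise-free directed drift is recovered within 2%", {
  cfg <- simulation_config(drift_speed = 0.5, noise_rms_s2s = 0,
                           loss_rate = 0, seed = 9)
  sim <- simulate_session(cfg)
  ev <- detect_events(sim$recording)
  m <- segment_metrics(ev)
  expect_equal(m$means$drift_speed, 0.5, tolerance = 0.02)
})

test_that("condition aggregation weights participants equally", {
  seg <- data.frame(
    participant = rep(c("P1", "P2"), each = 4),
    session = rep(c(1, 2), 4),
    label = rep(c("Point", "Point", "Circle", "Circle"), 2),
    polarity = "white-on-black",
    bcea = c(1, 1, 2, 2, 3, 3, 4, 4),
    saccade_rate = c(2, 2, 2, 2, 1, 1, 1, 1))
  summ <- aggregate_conditions(seg)

  # single participant, single session reduces to the segment values
  one <- aggregate_conditions(seg[1, ])
  expect_equal(one$grand$bcea, 1)

  # participants with values 1 and 3 -> unweighted grand mean 2
  expect_equal(summ$grand$bcea[summ$grand$label == "Point"], 2)
  expect_equal(summ$grand$bcea[summ$grand$label == "Circle"], 3)

  # per-participant weighting: extra sessions do not tilt the grand mean
  seg_extra <- rbind(seg, data.frame(participant = "P1", session = 3,
                                     label = "Point",
                                     polarity = "white-on-black",
                                     bcea = 1, saccade_rate = 2))
  expect_equal(aggregate_conditions(seg_extra)$grand$bcea[
    summ$grand$label == "Point"], 2)

  # permuting session order leaves all means unchanged
  perm <- seg[sample(nrow(seg)), ]
  expect_equal(aggregate_conditions(perm)$grand, summ$grand)

  # missing cells are reported
  expect_warning(aggregate_conditions(seg[seg$participant == "P1" |
                                            seg$label == "Point", ]),
                 "missing participant x condition")
})
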