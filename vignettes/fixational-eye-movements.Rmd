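---
title: "Analysing fixational eye movements with fixem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing fixational eye movements with fixem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixem)
```

## The problem

While a participant holds fixation on a target, the eyes keep moving: slow
meandering *ocular drift* is interrupted a few times per second by small,
fast *microsaccades*. Quantifying these fixational eye movements requires
an eye tracker with far better precision than ordinary video-based systems
provide (typical video RMS-S2S is around 2.4 arcmin, whereas retinal
trackers reach 0.07–0.6 arcmin), and a careful chain of signal processing:
event detection, exclusion rules, stability metrics, and aggregation across
trials and participants. `fixem` implements that chain for 30-s fixation
recordings sampled at several hundred hertz, along with a synthetic gaze
generator so every stage can be validated against known ground truth.

## The pipeline and its model

### Input and conventions

A recording is a time series $(t_i, x_i, y_i, v_i)$ with gaze in degrees of
visual angle and a per-sample validity flag. Conventions used everywhere:

* participant view, $+x$ rightward, $+y$ upward, origin at the calibrated
  zero point; directions reported in $[0°, 360°)$ with $0°$ rightward and
  $90°$ upward;
* half-open time intervals $[t_\mathrm{on}, t_\mathrm{off})$, 1-based
  sample indices;
* invalid samples keep their (missing) positions; nothing is ever
  interpolated across data loss.

Zero-point calibration pools the valid samples of the central-fixation
windows, discards the first 0.5 s of each window (so the saccade that
acquires the calibration target does not contribute), and takes the
per-axis **median**. The median rather than the mean makes the estimate
robust to microsaccades within the calibration fixations; calibrating an
already-calibrated recording returns an offset of exactly $(0, 0)$.

### Microsaccade detection

Detection follows the Engbert–Kliegl velocity-threshold method with its
conventional defaults. Velocity is a 5-sample moving-average derivative,

$$v_n = \frac{p_{n+2} + p_{n+1} - p_{n-1} - p_{n-2}}{6\,\Delta t},$$

with $\Delta t$ the segment's *median* sample interval (the stencil assumes
uniform sampling; the median is robust to timing jitter). The noise level
per axis is the median-based estimate
$\sigma = \sqrt{\langle v^2\rangle_{med} - \langle v\rangle_{med}^2}$ and
the threshold is $\eta = \lambda\sigma$ with $\lambda = 6$. Candidates are
maximal runs of at least 3 samples satisfying the elliptic criterion
$(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1$. Runs cannot span samples whose
velocity is undefined, so a data-loss run inside a candidate invalidates
it.

Candidates closer together than 20 ms (end of one to start of the next)
are merged, iterated to a fixed point, so post-saccadic oscillations are
not counted as separate saccades. Each surviving event's displacement is
the vector from the **last valid sample before onset to the first valid
sample after offset**, deliberately excluding the dynamic overshoot at
saccade end; events below 4 arcmin are then discarded. The displacement
filter runs *after* merging because merging changes event extents.

### Drift episodes and exclusion rules

Everything between saccades that is free of data loss and strictly longer
than 100 ms is coded as drift. The stretches before the first and after
the last saccade are included: treating them otherwise would discard most
drift in low-rate segments. Events are then filtered by two rules: the
first half second of each segment is warm-up (target-acquiring saccades
after the inter-trial mask), and saccades starting or landing — or drift
episodes whose mean position lies — more than 2.5° from the target center
are excluded. Every exclusion is counted per rule.

### Metrics

* **BCEA** (bivariate contour ellipse area), computed parametrically from
  the sample moments of the gaze positions pooled over selected events:
  $A = 2\pi k \sigma_x \sigma_y \sqrt{1-\rho^2}$ with
  $k = -\ln(1-P)$ and default coverage $P = 0.6827$, so the ellipse
  contains 68.27% of the positions of a bivariate normal cloud
  (1 SD). The parametric form follows the standard BCEA literature rather
  than an empirical quantile search.
* **Microsaccade rate**: selected saccade count divided by the analysed
  duration, taken as segment duration minus the 0.5-s warm-up (29.5 s for
  a 30-s trial). Lost time is not subtracted; at the sub-percent loss
  levels of the recordings this pipeline targets, the difference is
  negligible.
* **Saccade displacement and direction** from the same pre/post samples as
  detection.
* **Drift displacement/direction** (first to last episode sample),
  **path length** (summed adjacent-sample distances) and **speed**: the
  mean magnitude of the gradient of the position signal, second-order
  central differences at interior samples and one-sided differences at the
  episode edges (the behaviour of the conventional gradient routine).
* Aggregation averages within participant × target × polarity across
  sessions, then takes the **unweighted** mean across participants, so a
  participant with extra sessions or more events does not tilt the grand
  means.

### Density maps

Displacement vectors $(\Delta x, \Delta y)$ per target × polarity ×
participant are submitted to a Gaussian product-kernel 2D KDE with
per-axis Silverman bandwidths, discretized into 22 equally spaced contour
levels of which the lowest is omitted when plotting. A diffusion-based
bandwidth selector would be a drop-in refinement; the visualization, not
the bandwidth selector, is the content here.

## The synthetic generator

`simulate_session()` composes, sample by sample:

* **drift** — directed mode takes constant-length steps
  (`drift_speed / rate`, so realized step speed is exact) with a heading
  following a von Mises random walk (default concentration 10, giving a
  heading-decorrelation time of ~16 ms at 620 Hz) weakly pulled toward a
  bias direction; diffusion mode uses i.i.d. Gaussian steps of matching
  expected speed;
* **microsaccades** — dead-time-thinned Poisson times (default 1.8 Hz,
  150 ms refractory), lognormal amplitudes (median 0.22°, log-SD 0.35),
  directions from one or two opposed von Mises modes; each non-SWJ saccade
  additionally corrects a fraction (`recentering_gain`, default 0.85) of
  the current gaze offset, which is what keeps a 30-s trace within the
  2.5° exclusion radius; a configurable fraction of saccades is paired
  with an equal-and-opposite return after 200 ms (square-wave jerks);
  waveforms are raised-cosine position profiles with duration
  $\max(6\,\mathrm{ms},\ 21\,\mathrm{ms} + 2.2\,\mathrm{ms/deg}\times A)$
  — any smooth monotone profile with the right net displacement would do,
  since the pipeline measures displacement, not waveform shape;
* **sensor noise** — i.i.d. Gaussian with per-axis SD of half the target
  RMS-S2S (default 0.156 arcmin), which makes the measured RMS-S2S of a
  static trace equal the target (per step,
  $E[\Delta x^2+\Delta y^2] = 4\sigma^2$);
* **data loss** — Poisson episodes (default 0.065 Hz × 0.1 s ≈ 0.65%
  expected loss).

The defaults were chosen once to match the empirical regime of
high-precision retinal tracking of fixation: drift near 0.76 deg/s with a
predominant direction, saccade rates between 1.5 and 2.5 Hz with 0.1–0.4°
displacements, horizontal uni- or bimodal saccade directions with the
predominant drift direction opposite one mode, noise in the
0.07–0.6 arcmin range. What the generator does **not** emulate: pupil-size
and head-movement artefacts (the point of retinal tracking is their
absence), tremor, physiological drift dynamics (no self-avoiding-walk or
control-theoretic models), and blink kinematics around loss episodes.
Passing recovery tests on this generator therefore validates the
*pipeline's* correctness — detection, rules, metrics — not the realism of
any particular oculomotor model.

## Numerical choices and degenerate inputs

* Thresholds: a median-based $\sigma$ below $10^{-9}$ deg/s raises a
  degenerate-signal error rather than producing spurious detections on
  constant input.
* BCEA requires ≥ 3 points, non-zero variance per axis and
  $1-\rho^2 > 10^{-12}$; collinear clouds are an error, not area zero.
* Drift speed needs ≥ 3 samples, path length ≥ 2; both signal errors
  instead of returning silent zeros.
* RMS-S2S skips sample pairs spanning invalid samples; with no valid pair
  it errors.
* Ties at interval boundaries follow the half-open convention; a sample
  exactly at $t_\mathrm{off}$ belongs to the next trial.
* All generator randomness flows from a single integer seed; identical
  config and seed give byte-identical output. Detection contains no
  randomness at all.

## Validation problem sizes

The shipped tests validate: BCEA coverage and closed-form area on $10^5$
simulated points (±0.5% coverage); equivalence of the composed detector
with an independent brute-force per-sample scan on 100 random
2,000-sample segments, event for event; recovery on 20 simulated 30-s
sessions at 0.16 arcmin noise with net amplitudes ≥ 6 arcmin (≥ 95% hit
rate within ±10 ms of true onset, ≤ 0.1 Hz false alarms, mean displacement
error within max(0.5 arcmin, 10%)); drift-speed recovery within 5%
(noise-free; the central-difference estimate of a meandering path is
biased low by about $1/(8\kappa)$, ~1.3% at the default heading
concentration); the RMS-S2S calibration identity within 2%; and exact
behaviour of every merge/displacement/drift-duration/warm-up/eccentricity
rule on constructed fixtures.

## Known limitations

* Monocular only; no binocular conjugacy measures.
* $\lambda$ and $\sigma$ are estimated per segment; no adaptive
  re-estimation within a segment.
* The per-event peak speed uses the smoothed detection velocity, so it is
  attenuated relative to instantaneous peak velocity — fine for ranking,
  not for main-sequence peak-velocity fits.
* The BCEA is computed per segment and then averaged; pooling positions
  across sessions before computing BCEA would weight sessions by sample
  count and is deliberately not done.
* Reading proprietary eye-tracker binary formats is out of scope; the
  canonical input is the delimited-text dialect of `read_gaze()`, and
  adapter dialects map other column layouts onto it.

## A short end-to-end run

```{r example}
cfg <- simulation_config(duration = 30, seed = 7)
sim <- simulate_session(cfg)
sim

ev <- detect_events(sim$recording)
summary(ev)

m <- segment_metrics(ev)
m$means[, c("bcea", "saccade_rate", "saccade_displacement", "drift_speed")]
```
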