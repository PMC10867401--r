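---
title: "Methods: smart-insole plantar pressure analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smart-insole plantar pressure analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantarpress)
```

`plantarpress` analyzes 8-channel plantar-pressure recordings from a
capacitive smart insole. This vignette documents the models and procedures
the package implements, the tunable parameters and their defaults, the
numerical choices that were genuinely open, and what the synthetic data can
and cannot establish.

## The measurement model

Each insole sensor is a parallel-plate capacitor, `C = eps * A / d`, whose
porous composite dielectric is modelled as a two-phase mixture,
`eps = eps_air * V_air + eps_composite * V_composite`. Compression collapses
pores and thins the dielectric, so capacitance rises with pressure
(`capacitance()`, `mixture_permittivity()`).

The empirical pressure response is summarized by two regional sensitivities
of the relative capacitance change `S = (C - C0) / (C0 * dp)`: 0.0126 kPa^-1
on 0-200 kPa and 0.0038 kPa^-1 on 200-500 kPa. `calibration_curve()` models
the response as two exact linear segments joined continuously at the 200 kPa
breakpoint - the simplest functional form consistent with those two numbers.
The inverse map (`relcap_to_pressure()`) is the exact piecewise-linear
inverse; readings that invert below the 0.4 kPa detection limit are censored
to zero rather than raising, which keeps streaming conversion robust.
Hysteresis, creep and temperature dependence are bench properties of the
hardware, not algorithms, and are not modelled. Whether the eight channels
share one curve is unknown; the default is one shared curve with per-channel
override slots in `calibrate_series()`.

## Synthetic gait generator

No public recordings exist for this sensor, so the package ships a seeded
generator (`generate_posture_series()`, `generate_mixed_session()`) that
emulates the qualitative structure of the published per-posture traces:

* One gait cycle is 120 samples; the sampling rate defaults to 200 Hz so the
  0.6 s analysis window spans 120 samples. The hardware's true rate is not
  published; windows and steps are therefore defined in samples, with
  seconds derived from the configured rate.
* Per channel, a cycle is a half-sine (raised-cosine) loading pulse with a
  posture-specific peak, centre and width. Pulses are phase-ordered along
  the stance: heel strike (S7, S8) first, midfoot contour (S4), metatarsal
  push-off (S1, S3, S6), then toe-off (S2, S5). Peak loads are concentrated
  in the metatarsal and heel regions for every posture, matching the
  measured distribution. Standing is a constant heel-dominant load with no
  cycle structure.
* Amplitudes were fixed once at values a gait lab would call plausible for
  each activity (walking ~230-260 kPa peaks, running ~300-340 kPa, jump
  landings ~330-380 kPa, all within the sensor's 500 kPa range).
* Stochasticity: a per-cycle amplitude factor (sd 5 %), a per-cycle circular
  phase shift (sd 2 % of the cycle), and additive Gaussian sensor noise
  (sd 5 kPa), clipped at 0 kPa.
* Fatigue lowers peak load to 0.8x, widens the pulses by 1.3x, delays
  push-off by 5 % of the cycle and raises phase jitter 1.5x. The shape
  changes matter: windows are z-scored per channel before classification, so
  a pure amplitude rescaling would be invisible to the classifier; slower,
  flatter roll-over is also the physiologically expected signature of
  fatigue.

The generator reproduces per-posture periodicity, regional loading patterns
and class overlap, which is what the segmentation and classification
pipeline needs. It does **not** reproduce subject-specific waveforms,
bilateral gait, ground-truth kinetics, sensor drift or motion artefacts -
so a passing pipeline here shows correctness of the algorithms, not field
performance on human recordings.

## Full-foot pressure mapping

The eight discrete readings are interpolated to a continuous insole surface
with a cubic B-spline surface (`interpolate_map()`). Eight scattered points
cannot determine a tensor-product spline, so the control net is chosen by
minimizing a roughness functional - squared second differences (curvature)
plus a 0.5-weighted squared first-difference term - with a weak (2e-2)
pull toward the frame mean, subject to exact interpolation at the eight
sensor coordinates (a small KKT solve, 16 x 16 control net by default).
This was a genuinely open design point: a two-stage pipeline (scattered
interpolation to a coarse grid, then B-spline re-evaluation) was considered
and rejected because the intermediate re-gridding loses exactness at the
sensor sites, which the package treats as a contract (`map_value_at()` at a
sensor coordinate returns that sensor's reading to machine precision). The
gradient term and mean-shrinkage bound the cubic overshoot between sparse
constraints: over random frames the surface stays within 1.25x the largest
input, and it is clipped at 0 kPa. The surface is masked to a polygonal
insole silhouette; the mask, layout coordinates and medial/lateral side
assignments are configuration, since the physical sensor placement is only
published pictorially.

Static pronation (`classify_pronation()`) uses the asymmetry index
`(P_left - P_right) / (P_left + P_right)`, where the left set is the
outermost metatarsal plus heel sensor left of the foot axis (S6, S7) and the
right set their mirror (S1, S8). |index| <= 0.15 is NORMAL (the threshold is
not published; 0.15 separates the generator's postures cleanly and is
config); beyond it, left-loading is called overpronation and right-loading
underpronation, with a `side_convention` switch for the contralateral foot.
The 45 % figure is deliberately *not* used here - it belongs to the alert
engine, where it is defined.

## Long-term usage statistics

Pressures partition into four zones - low (0-50 kPa), medium (50-200),
high (200-400), very high (>400). The published zone table overlaps at its
boundaries; the package closes each zone on the left (50 kPa is MEDIUM,
200 kPa is HIGH, 400 kPa is VERY_HIGH) so occupancy times are exactly
conserved. For the same reason `high_pressure_time()` counts samples *at or
above* its threshold, making it exactly the HIGH + VERY_HIGH occupancy at
200 kPa - an identity the tests assert. (The alert engine, by contrast,
keeps the strict reading of "more than 30 s above 200 kPa": strict on both
pressure and duration.) Mean effective load excludes the low zone, and
channels that never reach 50 kPa report 0 with a flag rather than NaN.

Activity accounting counts heel strikes: local maxima of `max(S7, S8)` above
100 kPa with a 0.3 s refractory period, attributed to the posture active at
the peak. The height floor and refractory period are invented (the
reference system publishes demo totals, not its counting rule), exposed in
the config, and validated against the generator: noise-free walking recovers
the generated cycle count exactly, default noise stays within 2 %. Distance
is `(steps + run_steps) * stride_length`; energy uses a MET model
(walk 3.5, run 8, jump 10, stand 1.3; `kcal = 1.05 * mass_kg *
sum(MET * hours)`) and is documented as an estimate.

## Segmentation-assisted classification

Continuous recordings are cut by a sliding window of 120 samples stepped by
30 (`segment_series()`). Windows starting in the last 90 samples are
completed circularly by default, so an L-sample series yields exactly
`L / 30` windows when the step divides L - 150 cycles become 600 windows,
matching the reference pipeline's count; `circular_pad = FALSE` gives the
strict 597. Mixed windows take the label occupying more than half the
window; an exact 50/50 tie takes the later-occurring class, on the view that
the window's more recent half is the better evidence of current activity.

`make_split()` stratifies 80/20 per class (600 -> 480 train / 120 test) and
partitions the training set into five stratified folds of 96 per class for
cross-validation.

The classifier is a 1D CNN over 8 x 120 windows: conv(128, k7) - conv(128,
k7) - maxpool(2) - conv(256, k7) - conv(256, k7) - maxpool(2) - flatten
(256 x 30 = 7680) - dense softmax over six classes (856,838 parameters).
Kernel size, filter counts and depth follow the published architecture
optimization; activation (ReLU), padding (same), pooling (max), optimizer
(Adam, initial 1e-3), schedule (cosine decay to 0) and loss (categorical
cross-entropy) are unstated there and were fixed here once, chosen so the
layer arithmetic is well-defined and the loss curve decays smoothly. Windows
are standardized per channel with statistics from the training set only
(also togglable, since the original preprocessing is unstated). The network
is implemented in single-precision C++ (im2col + BLAS GEMM forward and
backward) because no deep-learning framework is available to R here and the
training loop is the package's core method; all stochastic steps (He
initialization, epoch shuffling) draw from one seeded generator, so runs
are reproducible on single-threaded BLAS.

Problem sizes: the package's reference experiment trains 50 epochs on 2880
windows (3600 windows, 600 per class). The synthetic classes are cleanly
separable, and held-out accuracy exceeds 95 % well before epoch 50; the
reference hardware experiment trained 200 epochs on human recordings that
are not public, so its exact 95.3 % is not reproducible and the synthetic
experiment stands in for it. Inter-class similarity of the raw signals -
the motivation for learned features - is quantified by
`posture_correlation()`, which flags class pairs with Pearson r > 0.3 as
strongly correlated.

## Alert engine

`scan_alerts()` (offline) and `alert_monitor()` (streaming, bounded state)
implement five rules and are equivalent by construction and by test:

* spike: any channel above 500 kPa, one event per maximal excursion;
* sustained: one channel above 200 kPa for *more than* 30 s (strict - a
  30.000 s excursion raises nothing);
* uneven: `|P_left - P_right| / max(P_left, P_right) > 0.45` persisting at
  least 1 s. The denominator is unstated in the source material;
  normalizing by the more loaded side is the default (it is the most
  conservative of side/sum/mean) and configurable. The 1 s persistence
  filter keeps single-frame flickers from paging the user;
* overuse: any channel at or above the 0.4 kPa detection limit continuously
  for more than 30 min;
* fatigue: a fatigued class label for at least 3 consecutive windows.

Events carry kind, onset, duration, channels and peak value. The streaming
monitor closes an excursion when its condition first fails (or at
`finalize()`), so event sets are invariant to how the stream is chunked.

## Known limitations

* Synthetic gait only; no claim transfers to human recordings without
  recalibration and revalidation.
* One insole; bilateral asymmetry is emulated by scaling the left-of-axis
  channels of a single foot.
* The calorie and distance models are first-order estimates.
* Pronation thresholds, peak-detection parameters and template amplitudes
  are package defaults, not published constants; all are configurable.

## A worked run

```{r example, eval = FALSE}
series <- generate_posture_series("WALK", n_cycles = 150, seed = 7)
windows <- segment_series(series)              # 600 windows
split <- make_split(rep(classifier_classes(), each = 600))
print(build_model(cnn_spec()))                 # layer table, 856,838 params
```

The full six-class experiment (generation, segmentation, split, 50-epoch
training, held-out evaluation) is scripted in `scripts/acceptance.R`.
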