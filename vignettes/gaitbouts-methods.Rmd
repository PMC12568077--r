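---
title: "Walking-bout segmentation from shank IMUs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking-bout segmentation from shank IMUs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbouts)
```

## The problem

Continuous shank- or ankle-worn inertial sensors record days of mixed
activity, of which only the walking bouts are of interest for gait analysis.
`gaitbouts` implements two complementary per-sample walking detectors for
tri-axial accelerometer (m/s²) + gyroscope (deg/s) recordings:

* a **harmonic frequency heuristic**: walking is periodic, so the spectrum of
  the mediolateral angular velocity shows a cadence fundamental and its
  integer harmonics;
* a **residual-convolutional + bidirectional LSTM classifier** trained on
  sliding windows of the raw six-channel signal, whose window predictions are
  aggregated back to a per-sample mask.

Both produce a Boolean `gait_mask`, from which bouts are extracted and
individual strides segmented (mid-swing and heel-strike events,
101-point time normalization for ensemble averaging).

## Preprocessing

Raw recordings pass through a fixed chain, each step exposed as its own
function:

1. **Calibration** (`calibrate_to_shank_frame`): a quiet-standing interval
   orients the gravity vector onto +z; a second rotation about the vertical
   aligns the dominant horizontal direction of a walking interval with the
   anteroposterior +x axis. Both rotations are rigid; the composite matrix is
   returned and tested for orthonormality (RᵀR = I within 1e−12). Since a
   principal direction is sign-ambiguous, the +x sign is chosen so walking
   anteroposterior acceleration is positively skewed (forward-progression
   convention), ties toward +x. A standing interval whose acceleration-norm
   RMS exceeds 1 m/s² is rejected as "not quiet".
2. **Downsampling** (`downsample`): zero-phase 4th-order Butterworth low-pass
   at 0.4 × target rate, then integer-factor decimation (e.g. 1600 Hz → 100
   Hz). Non-integer factors are an error rather than silently resampled.
3. **Label harmonization** (`harmonize_labels`): raw dataset labels map onto
   seven classes — static, walking, running, cycling, stair ascent, stair
   descent, other — or are dropped. The default PAMAP2 mapping keeps lying /
   sitting / standing as *static* and vacuuming / ironing as *other*; the
   exact retained-ID set is configurable because the source datasets'
   appendix-level label lists vary.
4. **Edge trimming** (`trim_activity_edges`): 500 samples are removed from
   each end of every contiguous activity run (runs ≤ 1000 samples vanish),
   excluding transition periods and labelling slop.
5. **Windowing** (`segment_windows`): 5-second windows (500 samples at 100
   Hz) with 50% overlap, taken strictly inside single-label runs — a window
   never spans a label boundary or removed samples, so every window has one
   unambiguous label.
6. **Static gate** (`filter_static_windows`): a static-labeled window is kept
   only if the RMS of its acceleration-norm *deviation* is strictly below 1
   m/s². The deviation is taken about the window's own mean norm (its gravity
   estimate): the raw norm of a gravity-bearing signal is ≈9.81 m/s² and
   could never fall below 1, so the deviation reading is the only
   self-consistent interpretation of an RMS gate at 1 m/s².
7. **Participant scaling** (`fit_participant_scaler` / `apply_scaler`):
   per-channel standardization fitted on each participant's *walking*
   samples only, then applied to all of that participant's windows. Channels
   with SD below 1e−8 keep scale 1 so constant channels cannot blow up.

The whole chain is deterministic: identical input and configuration give a
bit-identical window set.

## The classifier

The network is built and trained entirely inside the package (base-R
vectorised tensor operations with exact analytic gradients, verified against
finite differences in the test suite):

* input `(window_sz, 6, 1)` →
* conv 32 × (2×2), stride 2, same padding → batch norm → ReLU →
* conv 32 × (2×2), stride 1, same → batch norm,
* plus a convolutional shortcut (32 × 2×2, stride 2) from the input; add →
  ReLU → dropout 0.5 →
* flatten and reshape to a sequence of `window_sz/2` steps ×
  `(n_channels/2)·32` features →
* bidirectional LSTM (64 units per direction by default) → dropout 0.5 →
* dense softmax over the activity classes.

For the default 500 × 6 input the post-residual feature map is
`(250, 3, 32)` — 24,000 values — reshaped to 250 time steps of 96 features.
Two points in this block are underdetermined by the published description and
were resolved as follows: the flatten-then-recurrent step is implemented as a
reshape that *preserves the temporal axis*, so the recurrent block sees the
250 downsampled time steps in order (a flat 24,000-vector fed to an LSTM as
one step would make the recurrence vacuous); and the recurrent width (64 per
direction) and "same" convolution padding follow the conventions of the
architecture family this model extends. Both are configurable.

Training minimises sparse categorical cross-entropy with Adam (learning rate
1e−3, the optimiser's conventional default), batch size 64, early stopping on
validation loss with patience 10 and restoration of the best-epoch weights
("best model based on minimized loss" is read as *validation* loss, the only
reading consistent with early stopping). One integer seed fans out to weight
initialisation, shuffling and dropout; training is reproducible on a fixed
BLAS. Train/validation/test splits must be subject-disjoint — the window sets
carry subject ids and `har_train` refuses shared participants.

Window probabilities become a per-sample mask (`predictions_to_mask`): each
sample's walking proportion over the windows covering it must strictly exceed
0.5. Ties at exactly half are *not* walking. The harmonic detector aggregates
its window calls with the same rule so the two methods are directly
comparable.

## The harmonic detector

10-second windows slide at a 5-second hop over the mediolateral gyroscope. A
window is **active** when its raw RMS exceeds 50 deg/s (the rest threshold is
applied to the untrended signal). An active window is **gait** when the
one-sided amplitude spectrum — linearly detrended, Hann-tapered, scaled
`2|X|/N` — has prominent peaks at ≥ 2 of the first 4 harmonics of the
fundamental, where:

* the fundamental is the most prominent *qualifying* peak (prominence ≥ 5)
  inside the 0.5–3.0 Hz locomotor band — if no qualifying peak exists the
  window is not gait;
* harmonic *k* counts when a local spectral maximum with prominence ≥ 5 lies
  within `k·f₀ ± 0.15·k·f₀` (tolerance proportional to *k* tracks spectral
  leakage).

Numerical choices worth recording:

* **Scaling.** With the Hann taper, `2|X|/N` reads a sinusoid of amplitude A
  as ≈ A/2, so the prominence threshold 5 corresponds to ≈ 10 deg/s of
  harmonic amplitude. The full window length is kept (0.1 Hz resolution):
  Welch-style segment averaging was evaluated and rejected because 5-s Hann
  segments merge the 0.45 Hz-spaced harmonic ladder of very slow gait.
  The uncompensated scaling, together with the qualifying-fundamental rule,
  keeps broadband noise (e.g. 60 deg/s-RMS white noise) below the prominence
  threshold ≥ 95% of the time while genuine harmonics sit far above it.
* **Very slow gait.** A 0.45 Hz stride frequency lies below the band edge;
  the detector then locks onto the second harmonic as its fundamental and
  relies on the even-harmonic ladder. Detection survives at prominence 5 but
  not at higher foot-calibrated prominences — exactly the speed-dependent
  failure mode that motivates the shank adaptation.
* The hop (5 s) and the strict-majority per-sample rule mirror the
  classifier-side aggregation; trailing samples covered by no window inherit
  the last window's call.

## Bouts and strides

Maximal true runs of a mask become half-open `[start, end)` bouts (0-based,
optional minimum duration). Within a bout, mid-swing peaks are local maxima
of the mediolateral angular velocity with height ≥ 50 deg/s and separation
≥ 0.5 s (the height reuses the detector's rest threshold; the separation
bounds cadence at 2 strides/s — both configurable since the event-detection
literature varies). For each successive mid-swing pair the heel strike is the
largest resultant-acceleration peak in the *first half* of the interval (left
endpoint included). Strides run heel strike → next heel strike, gated to
0.4–4.0 s (wide enough for 0.3 m/s gait, excluding detection artifacts), and
are linearly interpolated onto 101 points — endpoints preserved exactly — for
ensemble averaging (`ensemble_average` returns pointwise mean and SD).

## The synthetic generator

Real labeled clinical recordings cannot ship with the package, so every
detector code path is exercised by `synth_walking` / `synth_static` /
`synth_other` / `synth_cohort`, which emulate the *statistical structure* the
pipeline assumes, with exact ground truth:

* **Walking**: per-cycle template — one dominant Gaussian mid-swing bump
  (width 8% of the cycle) plus a smaller negative stance bump on the
  mediolateral gyro, giving a fundamental plus a rich harmonic ladder; a
  decaying 15 Hz heel-strike transient on the vertical accelerometer peaking
  exactly at the planted time, 30% of a cycle after each mid-swing (inside
  the first half of the mid-swing interval); anteroposterior oscillation
  with positive skew; cycle-time jitter (CV 3%) and Gaussian channel noise.
  Planted mid-swing/heel-strike indices are returned as ground truth.
* **Speed strata**: speed maps to cadence and amplitude via a lookup —
  0.3 m/s → 0.45 Hz at 160 deg/s (40% of reference), 1.0 m/s → 0.9 Hz at
  400 deg/s, 1.4 m/s → 1.05 Hz at 500 deg/s — linearly interpolated. The
  anchors were chosen once so that slow gait remains *active* (RMS ≈ 54
  deg/s, above the 50 deg/s rest threshold) while its harmonic peaks weaken
  enough to reproduce the qualitative speed-dependent detectability: at
  prominence 5 the slow profile is mostly detected, at a foot-calibrated
  prominence of 17 it is mostly missed. None of the values is claimed to be
  physiologically exact.
* **Static**: gravity plus small noise (0.05 m/s², 1 deg/s) — passes the
  static gate by construction.
* **Other** (housework-like): strong non-periodic low-frequency wander
  (0.3–0.65 Hz) plus weak broadband motion to 8 Hz, so windows are active
  (RMS > 50 deg/s) yet show no stable harmonic structure — the
  active-but-not-gait path.
* **Cohorts**: a master seed derives per-subject seeds; each subject gets
  ±20% amplitude and ±10% cadence perturbations. The default clinical-style
  schedule is ≈48% static / 52% walking, matching the labeled in-clinic
  composition structure.

What passing tests on these signals show — and what they do not: the
generator validates the *machinery* (event arithmetic, spectral criteria,
aggregation rules, training dynamics) under controlled truth; it does not
establish clinical accuracy on real gait, which varies in ways the template
does not model (sensor drift and saturation, turning, shuffling,
asymmetries, footwear and surface effects).

## Problem sizes and numerical notes

* Classifier tests and the acceptance script train on 2-second windows at 50
  Hz (sequence length 50, 32 recurrent units per direction, 12-subject
  cohort, 10/1/1 split) — a scaled-down configuration of the same
  architecture chosen so the full demonstration trains in about a minute on
  one CPU core; the default configuration (500-sample windows, 64 units) is
  what the shape and parameter-count tests pin down.
* Batch norm uses ε = 1e−3 and momentum 0.99 on running statistics; Adam
  uses ε = 1e−7; LSTM forget-gate bias initialised to 1, recurrent weights
  orthogonal, all other weights Glorot-uniform.
* Softmax ties break toward the lowest class index; zero-denominator metric
  ratios are reported as `NaN` with a warning; rounding to 2 decimals happens
  only at presentation.
* Wilson score intervals (symmetric-z closed form) are attached to
  evaluation tables; they always contain the point estimate and stay inside
  [0, 1].

## Known limitations

* The PAMAP2 composition counts reported alongside the original analysis
  depend on the full downloaded dataset and its appendix-level label mapping;
  the package ships the exact counting machinery (reader, harmonization,
  trimming, composition) verified on constructed fixtures, and the retained
  PAMAP2 ID set is configurable.
* The harmonic detector is tuned for shank placement; foot-mounted
  parameterizations and multi-signal ensembles are out of scope.
* No orientation estimation beyond the two-step static+walking alignment; no
  sensor-fusion filtering; no spatiotemporal gait metrics beyond event times.
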