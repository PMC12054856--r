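---
title: "Detecting time in bed from hip-worn accelerometry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting time in bed from hip-worn accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tibhip)
```

## The problem

Hip-worn accelerometers are the workhorse of physical-activity surveillance
in large cohorts, and 24 h wear protocols mean the devices also record the
nights. Time in bed (TiB) — the interval from going to bed to getting out
of bed, a superset of sleep — can in principle be read off the signal: in
bed, the device measures an almost constant gravity vector in a lying
orientation, interrupted only by sparse posture turns; out of bed it
measures upright orientations with frequent movement bursts. `tibhip` casts
this as per-minute binary sequence labelling with a recurrent network, plus
the preparation, quality-control and evaluation machinery around it.

## Signal preparation

**Autocalibration.** Accelerometers drift: each axis acquires a small gain
and offset error, so resting measurements no longer lie on the unit-gravity
sphere. We detect *stationary epochs* (10 s windows whose per-axis SD is
below 13 mg), take their per-axis means as noisy observations of pure
gravity, and fit a per-axis affine correction `a' = g·a + o` by iterated
least squares: each epoch mean is projected to its closest point on the
unit sphere and the correction refitted against those targets, until the
mean absolute deviation of the calibrated vector magnitude from 1 g stops
improving by more than 1e-6 g (cap: 100 iterations). The update is only
accepted while the residual does not increase, so the residual path is
monotone. The fit requires at least 10 stationary epochs whose means span
at least 0.3 g of range on two or more axes; sparser inputs (short or
motionless recordings) fall back to identity coefficients with a
diagnostic flag rather than failing — the pragmatic behaviour for pipeline
use. Offset is applied after gain so coefficients remain interpretable.
No temperature covariate is used (the synthetic signal has no temperature
channel).

**Per-minute aggregation.** The model consumes one data point per minute:
the per-axis arithmetic mean of all raw samples in `[minute, minute + 1)`,
with partial leading/trailing minutes dropped. Movement in bed is largely
static, so minute resolution preserves the discriminative content (lying
vs. upright orientation, presence of bursts) while keeping sequence lengths
tractable for recurrent modelling. The aggregate could alternatively be a
decimated sample or a vector magnitude; the mean is the simplest
magnitude-preserving choice and the one we fix throughout.

**Cohort normalization.** Each axis is z-scored with the mean and SD of the
per-minute acceleration pooled over *all minutes of all training subjects*.
The statistics are fitted on the training portion only and frozen for
validation and test data; the cross-validation harness refits them inside
every training fold and stamps each series with a provenance string, which
`predict_lstm()` checks, so train/validation leakage through the
normalizer is structurally impossible. (A whole-dataset variant would
differ negligibly here but is a leakage risk, so per-fold fitting is the
default and only documented behaviour.)

## Augmentation

Four stochastic operators, applied per crop in the fixed order
crop → flip → reverse → noise (the order matters for reproducibility
because noise draws do not commute with the others):

| operator | default | what it emulates |
|---|---|---|
| random crop | 100 crops/sequence/pass, length ~ U{5 min, …, T} | variable recording lengths, partial nights |
| flip | p = 0.5, negates x and y | device worn upside down |
| reverse | p = 0.5 | inverse order of in-bed/out-of-bed transitions |
| Gaussian noise | p = 0.1, σ = 0.1 | sensor noise, between-device variation |

Two interpretation choices deserve note. "Upside down" is implemented as
negating the vertical and medio-lateral axes — the 180° rigid rotation
about the anterior–posterior axis that physically happens when a hip band
is flipped — rather than negating all three axes; the axis set is
configurable. The noise σ of 0.1 is in *normalized* units, because
augmentation runs after z-normalization in the training pipeline; 0.1 g of
raw noise would dwarf genuine rest-level signal variation (~10 mg). Flip
and reverse are involutions, commute with each other, and preserve vector
magnitude and total TiB exactly — properties the test suite asserts.
Crops are drawn fresh on every pass rather than cached, keeping effective
sample diversity high; fixing the augmentation seed makes a batch
bit-reproducible.

## The sequence labeller

A stacked uni/bi-directional LSTM (input: the 3 normalized axes per
minute) with a logistic readout produces a per-minute in-bed probability;
the binary track thresholds at 0.5 with no post-hoc smoothing. The
recurrent cell, backpropagation through time and the Adam step are written
in C++ (RcppArmadillo); the gradients are verified against central finite
differences in the test suite, and bidirectional models are always run on
whole sequences (never split), as the backward pass has no valid stateful
carry-over.

Training controls are deliberately plain: Adam at learning rate 1e-3,
gradient-norm clipping at 5, per-minute binary cross-entropy, one
augmented crop per gradient step. We chose single-crop steps over padded
mini-batches because crops have very different lengths and the models are
small enough (thousands of parameters) that batching buys little; the
step-based early stopping this enables — validation loss on a held-out
20 % of training subjects every 250 steps, stop after 4 evaluations
without an improvement of at least 5e-3 — reacts within the first pass on
easy problems instead of waiting for epoch boundaries. The `min_delta` of
5e-3 is on the BCE scale (chance level ≈ 0.69); smaller gains do not move
a 0.5-thresholded labeller. All controls are overridable in
`model_config()`.

**Hyperparameter search and selection.** `cross_validate()` partitions
*subjects* (never minutes, never days) into k = 10 folds and scores each
grid cell — {1, 2, 4} layers × {1, 2, 4, 8, 16, 32, 64, 128} cells ×
{uni, bi} — by mean ± SE validation accuracy. `select_model()` then picks,
among the cells within one SE of the best mean accuracy, the one with the
fewest parameters (ties broken by layers, then cells, then
directionality): accuracy first, sparsity as the principled tie-break. The
package default architecture is bidirectional with 2 layers × 16 cells, a
desk-scale setting that the bundled experiments show is already saturated
on synthetic cohorts; larger cells from the grid behave identically in
kind.

## Non-wear detection

On the raw-rate signal (not minute aggregates), 60 min windows advancing
by 15 min are flagged as non-wear when at least 2 of the 3 axes satisfy
*either* SD < 3 mg *or* range < 50 mg; flagged windows are unioned into
maximal episodes. Comparisons are strict, and the axis count applies to
the disjunction of the two criteria per axis (the alternative reading —
range-only for the 2-of-3 count — is rejected as asymmetric). The detector
is tested for exact equivalence against a brute-force window enumeration,
and for the monotonicity that lowering the SD threshold can only shrink
the flagged time.

## Annotator quality control

Dual-annotator agreement is intersection-over-union on TiB interval sets,
computed in continuous time on the intervals themselves (exactness; the
minute-rasterized variant is kept as a cross-check and agrees within one
boundary minute per interval, exactly so on minute-aligned sets).
Recordings are kept only when IoU exceeds 0.9 *strictly*, and consensus
labels are the annotator intersection, hence a subset of either rating.
Two empty sets are defined to agree (IoU 1): vacuous agreement, logged as
a convention since real annotation pairs are never both empty.

## Day-level evaluation

Days are anchored at 12:00 noon — the convention for 24 h recording
protocols, where device handover happens around midday so noon-to-noon
windows contain whole nights. A day is *full* iff all 1440 minutes are
present; daily TiB totals are computed on full days only, since partial
first/last days make totals incomparable. A day is an *outlier* iff its
predicted TiB is strictly below 60 min or strictly above 1380 min —
essentially all-or-nothing predictions. Both minute-pooled and
subject-level (two-stage averaged) metrics are reported, since the two
answer different questions; ratios with empty denominators are reported
absent, never as zero. Method comparison between paired daily estimates
uses Bland–Altman bias and 1.96·SD limits of agreement.

## The synthetic generator

Every stage is exercised on simulated recordings from `sim_config()` /
`simulate_cohort()`. The generator emulates the *structure* of free-living
hip recordings, with all randomness derived from one seed via per-subject
substreams (subject `i` of seed `s` is always the same recording):

* Recordings start at noon and last whole days; bed and rise times are
  drawn per night around 23:00 and 07:00 (SD 30 min), giving ~480 min of
  TiB per night.
* In bed: a constant unit gravity vector in one of four lying
  orientations (supine/prone/left/right, with a small per-segment tilt),
  instantaneous re-orientations at Poisson times (2 turns/h), plus 10 mg
  Gaussian rest noise.
* Out of bed: upright orientations re-drawn at 4 posture changes/h,
  activity bursts at 6/h of 1–5 min with 250 mg noise, the same rest
  noise floor.
* Non-wear: with probability 0.1 per daytime window, one episode of
  60–180 min of *exactly constant* signal (device flat on a table);
  a config flag can add sub-threshold jitter for robustness tests.
* Device error: an optional per-axis affine miscalibration applied to the
  whole emitted trace.
* Annotators: two tracks obtained from the truth intervals by Gaussian
  boundary jitter (SD 5 min) only — never added or dropped intervals — so
  the IoU filter's behaviour is governed by a single parameter.

The defaults above *are* the study conditions of the bundled experiments;
they were chosen once as conventional values for an adult cohort (no
empirical bed-time distribution is fitted) and are not tuned per test.
What the generator does **not** emulate: sleep-stage microstructure, gait
dynamics or any realistic high-frequency content (default sampling is
1 Hz; all operators take the rate as data), heart-rate or posture
channels, timezone/DST transitions (timestamps are naive local time), or
annotator structural errors. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that the model learns posture-coded
TiB; they do not certify accuracy on real device data, where the
in-bed/out-of-bed contrast is weaker and labelling noise is structured.

## Problem sizes and numerical choices

The bundled end-to-end experiment (`run_synthetic_experiment()`, also run
by `scripts/acceptance.R`) uses 60 subjects × 2 days at 1 Hz with 15
held-out subjects and the default bidirectional 2×16 model — a size chosen
so the whole experiment, including three repetitions over seeds in the
test suite, completes in minutes on a single CPU while leaving the
qualitative conclusions (accuracy far above baseline, calibration
recovery, QC keep rates) unchanged at larger sizes.

Other numerical conventions, gathered in one place: half-open
`[start, end)` intervals everywhere, with minute membership decided by the
minute's midpoint (no double-counted boundary minutes); stationary-epoch
detection at 10 s / 13 mg; calibration tolerance 1e-6 g, gains constrained
only implicitly (the fallback guards degenerate fits); probability
threshold fixed at 0.5; model checkpoints serialize weights as
17-significant-digit strings so they round-trip bit-exactly through JSON;
training determinism holds for a fixed seed on a fixed BLAS.

## Known limitations

* Validation is entirely synthetic; no claim transfers to any specific
  device or cohort without recalibration of expectations.
* The per-minute aggregate is fixed to the mean; high-frequency features
  (spectral content, counts) are intentionally out of scope.
* Timezone-naive timestamps: a DST transition inside a recording would
  shift the noon anchor.
* The calibration fit shares the spirit of published autocalibration
  schemes but is not numerically equivalent to any specific
  implementation.
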