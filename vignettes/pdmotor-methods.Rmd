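---
title: "Methods: from raw inertial signals to a motor-impairment classifier"
author: "pdmotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw inertial signals to a motor-impairment classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmotor)
```

## The measurement problem

Clinical motor examination for Parkinson's disease (PD) scores each task on
a coarse 0–4 scale by eye. Body-worn inertial measurement units (IMUs) —
one module per wrist, fingers and foot, each providing triaxial
acceleration and triaxial angular rate at 100 Hz — let the same exercises
be quantified objectively. `pdmotor` implements the full analysis chain for
a standardised eleven-exercise protocol: repetitive upper-limb tasks
(thumb–forefinger tapping THFF, hand open/close OPCL, pronation–supination
PSUP), tremor tasks (rest HRST, postural POST), repetitive foot-tapping
tasks (TTHP, HTTP, HETO, leg agility HEHE), a 360° turn (ROTA) and a 15 m
walk analysed both at the foot (GTAF) and at the swinging arm (GTAH). Each
exercise is performed twice per side; a trial contributes 3 s of static
baseline, 10 s of task (gait and turning run to completion), and 3 s of
tail.

The pipeline has five stages, each an exported module:

1. **Conditioning** (`condition_recording`) — task-specific Butterworth
   filters;
2. **Segmentation** (`segment_recording`) — characteristic times from
   threshold/zero-crossing state machines;
3. **Feature extraction** (`extract_features`) — 87 kinematic and spectral
   parameters per side (174 per subject);
4. **Selection** (`select_features`) — Wilcoxon rank-sum screening,
   Bonferroni correction, Spearman correlation pruning;
5. **Classification** (`run_benchmark`) — SVM (linear, Gaussian, cubic),
   random forest and Gaussian naive Bayes under stratified 10-fold
   cross-validation.

## Signal conditioning

Movement tasks are low-passed with a fourth-order Butterworth at 5 Hz —
below the 3.5–7.5 Hz parkinsonian tremor band but above voluntary movement
rates — and the gait tasks at 3 Hz (free-walking cadence is near 1 Hz).
The tremor tasks keep their oscillatory content (low-pass 15 Hz for rest,
20 Hz for postural tremor) and lose their continuous component through an
additional fourth-order 0.5 Hz high-pass.

Two numerical choices matter here and are deliberate:

* **Zero phase.** All filtering is forward–backward. Characteristic times
  feed every temporal feature, and a causal fourth-order filter would lag
  events by tens of milliseconds in a rate-dependent way.
* **Edge handling.** Signals are extended by an odd (point-reflected) pad
  of 3× the filter order and each pass starts from its step steady state
  (the classic `lfilter_zi` construction). Without this, a constant input
  does not even reproduce itself near the edges. With it, DC gain is exact
  to 1e-6 and the 3 s static lead-in is untouched.

The raw channels are retained alongside the filtered ones: the
acceleration-integral feature (IAV) and the tremor acceleration spectra are
computed from gravity-inclusive signals (below).

## Segmentation grammars

Each repetitive task is segmented on one informative angular-velocity axis
(e.g. the index-finger ω_y for THFF, the wrist ω_x for PSUP, the foot ω_y
for tapping and gait, ω_z for turning and arm swing). A movement cycle is
delimited by three characteristic times: start (signal exceeds a
task-specific threshold, from 10 deg/s for foot tapping up to 50 deg/s for
pronation–supination), peak (downward zero-crossing: the limb reverses),
and end (return to a small negative threshold such as −3 deg/s). Gait uses
the four classic events heel-off, toe-off, heel-strike, foot-flat; turning
uses burst detection (±50 deg/s, release at ±5 deg/s); arm swing uses
reversals inside a ±2 deg/s band after the swing exceeded 10 deg/s.

Implementation decisions the task descriptions leave open:

* **Arming.** The end rule (ω ≥ −3 deg/s) would fire immediately at the
  zero-crossing; it is armed only once the signal has first dropped below
  the end threshold. The same arming serves the foot-flat rule in gait.
* **Refractory period.** 50 ms between detections. Plausible tap rates are
  far below 20 Hz, so this suppresses only noise-induced double-triggers.
* **Resolution.** Events are located at the first sample past the
  crossing; at 100 Hz the 10 ms quantisation is far below the feature
  scales. No sub-sample interpolation.
* **Sides.** Tasks whose sign convention flips with body side
  (pronation–supination, arm swing, turning direction) are mirrored before
  segmentation, so one state machine per grammar serves both sides.
  Incomplete trailing cycles are discarded.
* The leg-agility task HEHE is segmented for completeness but its features
  are spectral only.

## Kinematic features

For the repetitive tasks: number of movements (count of end events), mean
frequency (inverse mean interval between consecutive end events),
amplitude, phase velocities, range variabilities
(`100·(max−min)/max` over per-cycle frequencies and amplitudes) and the
integral of the absolute acceleration magnitude (IAV), a proxy for energy
expenditure. The first and last movements are excluded from amplitude and
velocity averages: the first is typically exaggerated, the last truncated
by the stop cue.

**Amplitude with drift correction.** The movement angle is the trapezoidal
integral of angular velocity at the 10 ms sampling step. Integration drift
is removed per cycle by the zero-velocity-update principle: both cycle ends
are motionless, so the accumulated end angle is drift, and the linear ramp
towards it is subtracted before taking the cycle maximum. A constant gyro
bias contributes exactly that ramp and cancels to machine precision — the
property the unit tests assert at 1e-6 degrees.

**Gait.** Stride, swing and stance times and relative stance come directly
from the event times; the dorsiflexion range per stride is the range of
the integrated sagittal angle, offset by an initial pitch estimated as
`atan2(a_x, a_z)` (in degrees) averaged over the preceding foot-flat
interval (10 samples before the first stride). The convention here is that
a flat foot with the z axis along gravity reads 0°; since the range is
offset-invariant, this choice is cosmetic but is fixed and tested against
the generator. Turning yields time, step count and frequency, plus summed
between-step stance time and its fraction of total time.

**Heel-toe tapping.** Toe and heel excursions integrate the angular
velocity between alternating toe-off and heel-strike events; following the
defining formulas these per-interval integrals are used as-is (no drift
ramp), with a `drift_correct` switch available. The combined heel-toe
frequency uses the within-pair interval, branching on which event came
first.

## Spectral features

Rest/postural tremor and leg agility are analysed in the frequency domain
over the 3–13 s static window. The estimator is Welch's method — 256-sample
Hann-tapered segments, 50% overlap, one-sided density — whose band integral
satisfies Parseval against the signal variance within 2% (asserted in the
tests; a plain periodogram is available via `method = "periodogram"`).
Features are the average band power (band power divided by band width over
the reference band), the fundamental (peak) frequency, and percentage
power in the parkinsonian band 3.5–7.5 Hz and — for postural tremor — the
physiological band 8–12 Hz.

Choices the task descriptions leave open, fixed here:

* The **reference band** for percentages and average power is
  `[0.5 Hz, task low-pass cutoff]`: 0.5 Hz matches the tremor high-pass, the
  cutoff bounds the band actually retained. Band membership is half-open,
  so fractions over a partition sum to exactly 100%.
* The **acceleration-side signal** is the Euclidean norm of the raw
  triaxial acceleration, then filtered. The norm is orientation-invariant,
  and after the 0.5 Hz high-pass the gravity offset linearises away,
  leaving the tremor oscillation. Gyro-side features use the conditioned
  dominant axis.
* **HEHE** uses the acceleration-magnitude signal (movement conditioning,
  fundamental searched in `[0.5, 5]` Hz); spectral ties break to the lowest
  frequency.
* Signals are de-meaned before estimation, so the DC bin never leaks into
  the 0.5 Hz band edge.

## Feature table and selection

Per subject, exercise and side, the two trial values are averaged; left
and right stay separate columns because PD onset is typically unilateral.
The full schema is 39 lower-limb and 48 upper-limb parameters per side —
78 FEET, 96 HANDS, 174 FULL (`feature_schema()` enumerates it).

Every feature is screened with a two-sided Wilcoxon rank-sum test (HC vs
PD) at α = 0.05 — exact for group sizes ≤ 10, normal approximation with tie
and continuity correction otherwise. A Lilliefors-corrected
Kolmogorov–Smirnov normality p-value is recorded per feature to justify the
nonparametric choice; it gates nothing. Significant features form the PS
set. Bonferroni correction is applied within each feature's limb panel
(m = 78 for lower-limb features, 96 for upper-limb, configurable), giving
PS_B; with a per-panel family the FULL sets are exactly the unions of the
limb sets, which keeps the four datasets nested (PS_B ⊆ PS, PC ⊆ PS,
PC_B ⊆ PS_B). Correlation pruning runs separately within each
limb-and-side panel: candidates are visited in ascending p (lexicographic
tie-break), and a feature is dropped if its |Spearman ρ| ≥ 0.85 (with
correlation p < 0.05) against any kept feature — so of two strongly
correlated parameters only the more significant survives. Selection runs
once on the full cohort before cross-validation, reproducing the reference
workflow; a nested, leakage-free variant can be obtained by calling
`select_features` inside a manual fold loop.

Missing values are excluded pairwise per test; a feature missing in more
than half of either group is excluded from screening and flagged.

## Classification benchmark

Five classifiers — linear, Gaussian and third-degree polynomial SVM,
random forest and Gaussian naive Bayes — are evaluated on each dataset
(PS, PS_B, PC, PC_B) under each condition (FEET, HANDS, FULL), reusing one
stratified 10-fold partition (8 subjects per fold at n = 80) across the
whole 5 × 4 × 3 grid. Per fold, features are median-imputed and z-scored on
the training subjects only. SVM hyperparameters come from an inner 5-fold
grid search (cost 10^−3…10^3; kernel width around 1/p for the Gaussian
kernel); the forest size is the smallest power of two from 2¹ to 2¹² whose
out-of-bag AUC is within 0.005 of the best — a size/accuracy trade-off;
naive Bayes uses variance-floored Gaussian likelihoods. Metrics (recall,
specificity, accuracy, precision, F-measure with PD positive) are computed
from the single pooled confusion matrix over folds, which is why
cohort-level metrics are multiples of 1/40; the F-measure is the standard
precision–recall harmonic mean. Everything is reproducible bit-for-bit
from the input table and one integer seed.

## The synthetic cohort generator

No public recordings exist for this protocol, so the generator is a
first-class module: every pipeline stage is validated against signals with
known ground truth.

The dominant-axis angular velocity is built from velocity lobes —
half-sine by default, because their integrals have closed forms that make
the feature oracles analytic; the cohort profiles use raised-cosine lobes
(`lobe_shape = "raised_cosine"`), which are C1-continuous and survive the
5 Hz task filter with negligible ringing. Per-cycle periods and amplitudes
carry log-normal jitter; gait strides follow the heel-off/swing/heel-strike
lobe grammar with lobe areas chosen so the foot returns flat; tremor tasks
superpose sinusoids and white noise. Acceleration is synthesised as gravity
rotated by the integrated angle, plus a tangential lever-arm term aligned
with gravity and white noise — sufficient for IAV, foot-pitch and
acceleration-spectrum features without rigid-body simulation. The last
movement of a trial is generated slower and strongly reduced (35%
amplitude), as real subjects do on the stop cue; this is also why the
last cycle is excluded from amplitude averages.

The default HC regime uses movement rates and amplitudes typical of
healthy adults (e.g. finger tapping near 4.5 Hz, pronation–supination
excursions near 150°, gait cadence ~0.95 Hz, dorsiflexion range ~92°,
negligible tremor); the PD regime is bradykinetic (rates ×0.6–0.9,
amplitudes ×0.4–0.9 depending on task), doubles cycle-to-cycle
variability, adds a ~5 Hz rest tremor and a parkinsonian component to
postural tremor, reduces arm swing and dorsiflexion, and applies a 0.85
severity factor to one randomly chosen side per patient (unilateral
onset). Between-subject severity is log-normal (8% HC, 12% PD). These
regimes are illustrative of mild-to-moderate disease, chosen once for
plausibility — they are not fitted to any clinical dataset, and passing
the end-to-end test says the pipeline separates such regimes, not that it
reaches any particular accuracy on real patients.

What the generator does **not** emulate: linear translation of the limb
(only the lever-arm term), sensor bias instability and scale error, soft
tissue artefacts, hesitations/freezing, amplitude decrement across a trial,
or correlated multi-axis motion. Real recordings will stress the
segmentation thresholds harder than these tests do.

## Problem sizes and verification

The test-suite sizes are chosen to keep the full suite comfortably inside
a desk-scale run: segmentation ground-truth sweeps use up to 50 cycles per
grammar on both sides; the null calibration of the statistical layer uses
200 simulated 80-subject cohorts; the end-to-end check uses ten cohorts of
20 HC + 20 PD and asserts mean Gaussian-SVM accuracy ≥ 0.9 on FULL with
FULL ≥ max(FEET, HANDS). `scripts/acceptance.R` recomputes the same
quantities from a fresh start (five cohorts) and writes them as JSON.

## Known limitations

* Segmentation assumes the biphasic/gait grammar holds; severely
  fragmented movements (multiple sub-lobes per cycle) would be
  over-counted. The thresholds are the protocol's printed constants, not
  adaptive.
* Feature selection on the full cohort before cross-validation slightly
  optimistically biases the benchmark (kept for comparability; see above).
* At very fast tapping rates the 5 Hz conditioning attenuates the movement
  band itself; amplitudes are then systematically compressed, which is a
  property of the protocol's filters, not of a subject.
* Average tremor power depends on the chosen reference band; values are
  comparable within this pipeline, not across differently configured
  estimators.
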