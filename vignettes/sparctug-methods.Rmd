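---
title: "Methods: SPARC smoothness analysis of the instrumented TUG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPARC smoothness analysis of the instrumented TUG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparctug)
```

This vignette documents the models, parameter choices and numerical
decisions behind `sparctug`, and what its tests do and do not establish
about real recordings.

## Signals and conditioning

A recording is six uniformly sampled channels at 100 Hz: linear
acceleration in g on the vertical (V), mediolateral (ML) and
anteroposterior (AP) axes, and angular rate in °/s about the yaw, pitch and
roll axes, within acquisition ranges of ±8 g and ±250 °/s. Angular
*acceleration* channels are derived by central differencing of the rates
(`angular_acceleration()`); the rotation axes map to the anatomical labels
as yaw → V, pitch → ML, roll → AP. "Total" channels are per-sample
Euclidean norms of the three axes, mean-subtracted so the static gravity
magnitude drops out.

Movement onset is declared at the first index where the mean absolute
deviation of a 10-frame window from the quiet-baseline mean exceeds 3 times
the SD of the first 100 frames. Two details are our own: the deviation is
taken from the baseline *mean* (a gravity offset cannot mask onset), and
the SD is floored at `sd_floor = 1e-6` g so a perfectly constant baseline
cannot trigger spuriously. Onset is detected once, on the resultant linear
acceleration, and gates all channels; applying it per channel would
desynchronise them for no benefit.

DC is removed by mean subtraction and drift by least-squares detrending
(default) or a 1 s moving mean. A 1 s moving-mean window passes only trends
slower than roughly 0.25 Hz, well below the slowest TUG component of
interest.

## Phase segmentation

Turns are intervals where the smoothed (0.25 s moving average) yaw rate
exceeds 30 °/s, extended outwards to 5 °/s crossings, and kept when the net
yaw angle reaches 120° — both TUG turns are nominally ~180°, so this
threshold tolerates shallow, slow turning without admitting gait sway.
Postural transitions are the first and last pitch excursions whose peak
reaches 15°, delimited at 5% of their own peak (floored at 1°). None of
these thresholds is prescribed by the protocol; they were chosen once to
recover simulator ground truth and are all exposed in
`segmentation_config()`.

Two integration details matter. Yaw angle gets a constant-bias correction
estimated from the initial quiet window, *not* linear detrending: the
integrated yaw of a test with two same-direction turns is a monotone
staircase, and detrending it biases every net-angle estimate. Pitch angle
is additionally anchored to its baseline at both ends of the recording —
the test starts and ends seated upright — which removes the residual
gyro-bias random walk that a leading noise window cannot estimate away.

The five phases are assembled contiguously: sit-to-stand ends at the first
pitch excursion's end, walk 1 runs to the first turn, walk 2 between the
turns, and the fifth phase merges the pre-sit turn with sitting down (the
form in which it is analysed and reported); the internal end of that second
turn is kept as an attribute for diagnostics. Intervals are 1-based,
half-open `[start, end)`, so phase durations sum exactly to the full-test
duration. Walking phases deliberately include the gait initiation and
termination transients adjacent to them.

## SPARC

`normalized_psd()` is a rectangular-window periodogram of the
mean-subtracted segment, zero padded to four times the next power of two,
restricted to 0–10 Hz, and divided by its maximum there. Normalizing by the
band maximum (rather than the DC value) is forced by the DC removal:
accelerometers pick up gravity, and after mean subtraction there is no
meaningful DC reference, while max-normalization keeps the profile in
[0, 1] as the arc-length geometry requires.

`sparc()` returns the negative discrete arc length of that profile with the
frequency axis scaled by 1/(f_high − f_low). Before summing, the profile is
extended to the exact `[0, 10]` band edges by constant extrapolation;
without this, a grid starting at the first FFT bin would allow arc lengths
marginally below 1 and break the invariant SPARC ≤ −1. A flat profile
yields exactly −1; each isolated unit spike adds almost exactly 2.

Phase segments are tiled end-to-end ×4 (full test ×2) before the FFT.
Tiling a segment k times concentrates its periodogram onto every k-th bin,
sharpening true periodic peaks against the leakage floor — the reason a
few-stride phase still yields a usable spectrum. Tiling is distinct from,
and applied before, zero padding. The DC of each segment is removed before
tiling so copy junctions introduce no step.

Magnitudes depend on the estimator configuration: with the fine zero-padded
grid, broadband sensor noise contributes arc length over many bins, so
absolute values for noisy synthetic signals sit below the −3…−6 range
typical of human waist-worn recordings. All group comparisons in this
package are therefore about directions and invariants, not absolute SPARC
levels; the generator makes no attempt to match published group means.
A related subtlety: through the noise floor, full-test SPARC retains a mild
systematic dependence on segment duration, so cross-trial stability is
assessed on the walking-bout SPARC, which is also where the speed-stability
question is scientifically posed.

## Freeze index

`frequency_ratio()` is the squared 3–8 Hz band power over the squared
0.5–3 Hz band power, band powers being trapezoidal integrals of the PSD
over the bins in each band. The shared 3 Hz edge is assigned to the
locomotor band (`[0.5, 3]`, `(3, 8]`) — an arbitrary but fixed choice.
Computed on the anteroposterior linear acceleration over the full test,
mirroring where the index is conventionally read. Note the step harmonic
(~4 Hz) lives inside the freeze band, so even healthy gait has a small
positive FR; the index is interpreted relatively, and it is exactly
scale-invariant.

## Synthetic cohort

The generator exists so that every stage has ground truth. One subject is a
parameter set (`subject_profile()`); one trial (`simulate_trial()`) is built
from templates:

* walking bouts: harmonics at 2 and 4 Hz with Tukey envelopes, phase
  offsets across axes, and (for PD) slow random frequency jitter and
  amplitude modulation controlled by a single `spectral_broadening`
  parameter (~0.02–0.08 control, 0.15–0.35 PD) — the "broad band of
  comparable dominant frequencies" phenotype;
* turns: tapered yaw-rate pulses integrating to ~180°; postural
  transitions: Hann-shaped pitch excursions (40°) with V/AP acceleration
  bursts;
* PD tremor: three independent, bursty, frequency-wandering 4.5–6.2 Hz
  sub-components scaled by the broadening parameter, added to rates and
  (weakly) accelerations. A single strong tremor line would *dominate* the
  max-normalized spectrum and paradoxically flatten everything else, so the
  band structure is essential;
* PD fragmentation: step-rate amplitude ripple on the turn and postural
  templates (hesitant, "en bloc" transitions), again scaled by broadening;
* freeze episodes: Hann-windowed 4–7 Hz bursts of stated intensity that
  locally suppress the locomotor harmonics; controls have none by
  invariant;
* sensor model: white noise of 0.02 g and 0.5 °/s (MEMS-typical in-run
  figures), a 1 g gravity offset on V, and hard clipping at the ±8 g /
  ±250 °/s acquisition ranges;
* phase durations: drawn per subject around means summing to 9.15 s
  (control) and 14.04 s (PD); walking phases shrink 4% per trial,
  emulating task learning — so trial effects exist in durations but not in
  smoothness.

Clinical scores are linear-plus-noise functions of a degradation score
(broadening plus total freeze intensity), clipped to instrument ranges
(UPDRS items 0–4, FOG-Q 0–24, H&Y 1–5, MMSE capped at 30), giving the
correlation stage a known monotone ground truth. All randomness flows from
one cohort seed: subject parameters and per-trial seeds are drawn under it,
and freeze-episode carriers use a derived sub-stream so that a
zero-intensity episode leaves a trial bit-identical.

What the simulator does *not* emulate: biomechanically valid joint
kinematics, realistic double-support timing, sensor-orientation error,
gravity re-projection during trunk lean, or the amplitude statistics of
real pathological gait. Passing tests establish that the pipeline's
detectors and metrics behave correctly on signals with the assumed
spectral and temporal structure — not that the specific thresholds are
optimal for any particular device or cohort.

One known limitation worth stating: on the rectified "total" channels
during the merged turn-and-sit phase, the control group's faster pre-sit
turn produces a broad transient spectrum of its own, so that channel-phase
cell does not separate the groups (and its within-cohort clinical
correlations are unreliable) even though all eight channels separate
clearly on the full test. The real counterpart of this caveat is that not
every channel × phase cell discriminates in human data either — the
sit-to-stand phase notably lacks group effects.

## Statistics

`anova_group_trial()` fits `lm(y ~ group * trial)` and reports Type II sums
of squares (via `car::Anova`): each main effect adjusted for the other,
ignoring the interaction — the appropriate decomposition for the heavily
unbalanced 31 vs 6 design, and identical to Type III on balanced data (a
property the tests check, along with an explicit model-comparison oracle
and the ~5% Type-I rate on 1,000 null cohorts). Post-hoc pairwise cell
contrasts come from `emmeans` with Sidak adjustment, `m` being the number
of contrasts performed. Correlation maps report unadjusted p-values flagged
at 0.05, the form in which such tables are printed; Sidak-adjusted columns
are available via `sidak = TRUE`.

Power calculations use the noncentral t distribution directly
(ncp = d·√(n₁n₂/(n₁+n₂)), df = n₁+n₂−2). For the design anchor —
d = 1.57/0.79 ≈ 1.99, α = 0.05, power 0.90 — the one-tailed convention is
the one under which the smallest sufficient group size is 6 (power 0.940;
n = 5 gives 0.888); two-tailed gives 7. We therefore treat the one-tailed
reading as the design's convention and say so prominently. The
correlation sample-size helper uses the Fisher-z approximation
(n = ((z_α + z_β)/atanh r)² + 3), which for r = 0.65, α = 0.05, power 0.95
gives 22 one-tailed and 25 two-tailed; exact (non-approximate) methods can
differ by a unit or two, so this routine is a generic design tool rather
than a quantity the test suite pins down. Retrospective power for an
observed standardized difference of 2.11/1.9 at 31 vs 6 evaluates to 0.68
two-tailed under the same noncentral-t machinery; power software differs in
conventions (tails, approximations) for this computation, and no particular
external figure is targeted.

## Problem sizes

The default verification scale, chosen to exercise the full study design:
one cohort of 31 PD + 6 control subjects × 3 trials (111 recordings,
~9–14 s each at 100 Hz) for the direction and dissociation checks; 50
seeded trials per noise level for segmentation recovery; 1,000
statistics-level null cohorts for ANOVA calibration. The full test suite
runs in about a minute on one CPU.
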