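---
title: "Methods: from shoe-mounted inertial signals to cross-validated gait classification"
author: "imugait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from shoe-mounted inertial signals to cross-validated gait classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

## The measurement model

`imugait` analyses recordings from a pair of shoe-mounted inertial
measurement units, each providing a 3-axis accelerometer (range ±6 g,
sensitivity 300 mV/g) and a 3-axis gyroscope (range ±500 deg/s,
sensitivity 2 mV per deg/s), sampled at 50 Hz. Subjects perform three
standardized leg-function tasks:

* **10-meter walk** — four passes of a 10 m distance; the turns between
  passes are excluded from analysis via recorded pass boundaries;
* **heel-toe tapping** — 20 s of rhythmic tapping;
* **circling** — 20 s of foot circling.

`raw_to_physical()` converts zero-centered millivolt readings with the
nominal sensitivities and clips silently (but counted) at the range
limits. Real devices additionally need a device-specific bias
calibration; that step is deliberately out of scope so the conversion
stays pure and testable.

For the two timed tasks, analysis uses a fixed 15 s window
(`task_analysis_window()`). The window starts after a 2.5 s lead-in —
movement initiation is transient-rich and rater-cued, so the first
seconds are unrepresentative — and shifts earlier (then truncates, with
a flag) when a recording is too short. Both constants are arguments, not
magic numbers.

## Step segmentation

Step-dependent features require per-step sample intervals. No standard
exists for segmenting steps from a heel-mounted gyroscope, so the
package uses a deliberately simple, deterministic procedure
(`segment_steps()`):

1. band-pass the gyroscope z-axis to 0.5–8 Hz (2nd-order Butterworth,
   zero-phase via forward–backward filtering) — below 0.5 Hz is posture
   drift, above 8 Hz is noise and tremor irrelevant to step timing;
2. detect mid-swing angular-velocity extrema as signal peaks with
   topographic prominence ≥ 50 deg/s and ≥ 0.4 s separation (both
   configurable; a polarity flag accommodates mirrored sensor
   mountings);
3. place step boundaries at midpoints between consecutive peaks, the
   first/last step bounded by the pass edges;
4. drop steps with durations outside [0.3 s, 3 s].

Prominence rather than raw height makes detection invariant to baseline
offsets; the separation rule caps cadence at 150 steps/min, which
comfortably covers pathological and healthy gait. Steps never straddle a
pass boundary, so turning segments cannot contaminate step statistics.
A signal in which no peaks clear the threshold yields an *empty* step
list, not an error: downstream, every step-dependent feature of that
subject is flagged missing and later imputed (see below).

## The 694-feature bank

Features are instantiated over a fixed grid of definition × channel ×
task × foot (`build_feature_catalog()`), in three families:

| family | definitions | channels | tasks | per foot | total |
|---|---|---|---|---|---|
| step (gyro-z only) | 5 | 1 | walk | 5 | 10 |
| step (all channels) | 6 | 6 | walk | 36 | 72 |
| sequence | 8 | 6 | all 3 | 144 | 288 |
| frequency | 9 | 6 | all 3 | 162 | 324 |

yielding 694 features per subject: 286 for the walk and 204 each for
tapping and circling. These counts are asserted programmatically at
catalog construction; they are the load-bearing structural contract of
the package. Step features are computed per detected step and averaged
over all steps of the subject; sequence and frequency features are
computed on the pass-concatenated walk signal or the 15 s window of the
timed tasks.

The gyro-z step definitions are step duration, per-step maximum,
minimum, min–max difference and energy; the all-channel step
definitions are per-step mean, variance, RMS, skewness, kurtosis and
mean absolute first-difference. Sequence definitions: min–max
difference, population variance, RMS, amplitude-histogram entropy,
regression line through all local extrema, mean, zero-crossing rate and
mean absolute first-difference. Frequency definitions: dominant
frequency (with parabolic peak interpolation), amplitude at the
dominant frequency, band energies in the locomotor (0.5–3 Hz) and
tremor (3–8 Hz) bands, windowed locomotor band energy (5 s windows,
2.5 s overlap, averaged), the Wiener–Khinchin PSD integral over
0.5–3 Hz, the temporal regression of 2.5 s-windowed band energy,
spectral entropy and spectral centroid. Every definition with a
published description is implemented to that description; the remaining
slots of the grid are standard time/frequency descriptors chosen so the
printed family counts are reproduced exactly. The bank is
count-conformant by construction, but no claim is made that the
unpublished original operator list is reproduced verbatim.

### Numerical conventions

Choices the underlying description leaves open are fixed once and used
consistently, so within-cohort comparisons are unaffected:

* **Spectral normalization.** After mean removal, one-sided energies are
  `|X_k|^2 / N`, doubled off DC/Nyquist, so band energies over a
  partition of [0, Nyquist] sum exactly to the time-domain energy
  (Parseval; this identity is a test).
* **PSD route.** The PSD feature goes through the biased
  autocorrelation, Fourier-transformed on the `2N−1` grid. For the
  biased estimator this provably coincides with the zero-padded
  periodogram, which the tests verify to 1e-9. Note that on this grid a
  finite tone is never bin-aligned, so rectangular-window leakage caps
  band concentration near 99.7 % rather than the bin-aligned ideal.
* **Windowing.** Rectangular windows after mean removal; no taper. The
  energy-trend regression uses 2.5 s windows with 50 % overlap.
* **Entropy binning.** 16 equal-width bins over the observed amplitude
  range (configurable); a constant signal has entropy 0 by definition.
  Range-relative binning makes the descriptor invariant to positive
  rescaling.
* **Extrema.** Strict inequality against both neighbours; plateaus
  contribute their first sample. A sequence with fewer than two interior
  extrema yields a flagged missing value. One subtlety found while
  validating: the extrema regression of a *pure sinusoid* is zero only
  when the extrema sequence is time-symmetric (e.g. a cosine over whole
  periods); a sine over whole periods starts on a maximum and ends on a
  minimum and has a small negative slope. The operator is correct; the
  naive expectation is not.
* **Degenerate inputs.** Operators that cannot be computed (all-zero
  spectrum, no steps, too-short signals) return missing values inside
  `extract_features()` — never errors — and missing entries are imputed
  only at the modelling stage, with training-portion medians computed
  inside every cross-validation split. Extraction itself stays pure.

## Feature selection

Selection composes a filter and a wrapper, in that order:

1. **Information gain** (`information_gain()`): each feature is
   discretized into 10 equal-frequency bins (tied quantiles merged) and
   scored by the mutual information with the class label, in bits.
   Equal-frequency binning makes the score invariant to monotone
   transforms. Features are ranked and the top 50 retained.
2. **Sequential forward selection**
   (`sequential_forward_selection()`): greedily add the candidate that
   maximizes 5-fold inner stratified-CV *balanced* accuracy of the
   configured classifier; ties break by higher information gain, then
   lower column index. Stop after 3 consecutive non-improving additions
   or at 25 features, returning the best-accuracy prefix.

The filter-then-wrapper order bounds the wrapper's cost; balanced
(rather than raw) accuracy is used as the criterion because the report
metric is the balanced classification rate and cohorts are not exactly
balanced. Both the stopping patience and the cap are configurable — the
cap exists because a greedy wrapper under noise occasionally "improves"
by chance, and unbounded growth would only amplify overfitting.

## Classification and evaluation

Four classifier families are provided behind one interface
(`classifier_spec()`, `train_classifier()`):

* **LDA** — pooled within-class covariance with a diagonal shrinkage of
  `1e-4 ×` the mean diagonal, so rank-deficient training sets are
  regularized rather than fatal;
* **AdaBoost** — discrete AdaBoost.M1 over depth-1 threshold stumps,
  10 iterations by default; stump search is exhaustive over features,
  polarities and thresholds between distinct sorted values, with a
  documented deterministic tie-break (first in feature/polarity/
  threshold order);
* **SVM** — linear and RBF kernels via `e1071::svm`, with the cost grid
  {1, 5, 10, 15, 20, 25, 30} (and a gamma grid for RBF) resolved by
  inner 5-fold balanced accuracy when more than one value is given.

LDA and SVM inputs are z-scored with training statistics; AdaBoost is
not standardized because stump thresholds are scale-equivariant.

Evaluation (`cross_validate()`) is stratified 10-fold cross-validation:
fold sizes differ by at most one, per-class counts per fold differ by at
most one, and assignment is deterministic in the seed. Inside every
fold, imputation and feature selection are re-run on the training
portion only — selection outside the CV loop is the textbook way to leak
— and a config flag (`fixed_subset`) supports evaluating a frozen
feature set instead, as in an independent-validation design
(`run_holdout_validation()`, which refuses overlapping subject ids).

Confusion counts are pooled over folds and the report metrics computed
from the pooled table: sensitivity, specificity, positive predictive
value, and the balanced classification rate defined as
(sensitivity + specificity)/2, reported as percentages and rounded
half-away-from-zero for tabular output. Pooling (rather than averaging
per-fold metrics) is used because a single pooled confusion table is
what an independent-validation confusion narrative corresponds to.
On the reference validation confusion of 32 true positives, 10 false
negatives, 33 true negatives and 6 false positives this yields 76 %
sensitivity, 85 % specificity and 84 % PPV; note the balanced rate of
those counts is 80.4 %, which the package reports as computed.

## The synthetic cohort generator

No public recordings exist for this kind of two-cohort shoe-sensor
study, so the package ships a generator (`sim_config()`,
`simulate_cohort()`) whose single effect-size knob `delta` controls
group separation. Controls walk with stride frequency ~N(1.0, 0.08) Hz
and gyroscope-z swing amplitude ~N(100, 10) deg/s; each subject gets
three harmonics with private phases, smoothly jittered cycle timing
(CV 3 %), cross-axis leakage, accelerometer analogues scaled to sub-g
range, and white sensor noise (3 deg/s, 0.03 g). The patient group at
effect size `delta` is slower (−0.15·delta Hz on the stride frequency,
with proportional analogues for tapping and circling), smaller in
amplitude (×(1 − 0.3·delta)), more variable in cycle time (×(1 +
delta)) and carries an added 5 Hz tremor-band component (5·delta
deg/s). At `delta = 0` the two groups are draws from the same
distribution. Synthetic UPDRS-III scores are a documented monotone map
of the effect size (centred at 8 + 10·delta, SD 4, clamped to [1, 50])
with Hoehn & Yahr stages derived from the 0–12 / 13–22 / 23+ bins —
they exist solely to exercise the subgroup contrasts.

The generator makes the classical discriminative descriptors (dominant
frequency, RMS, band energies, per-step range) carry genuine group
signal, and its walk signals segment into the expected number of steps
at the default detector settings. It does **not** model gait
biomechanics: no double support, no heel-strike/toe-off structure, no
freezing episodes, no asymmetric disease progression. Consequently,
passing end-to-end tests demonstrates that the pipeline recovers
separations *of the kind and size simulated* — it says nothing about
classification accuracy on real patients, which depends on unpublished
recordings.

## Problem sizes and reproducibility

The shipped experiments use cohorts of 30 + 30 simulated subjects with
10-fold cross-validation and LDA as the wrapper classifier — large
enough that a strong simulated effect (`delta = 2`) is recovered at
>90 % balanced rate while the binomial noise on a 60-subject pooled
confusion (~6 points SE) is kept in view when comparing conditions;
effect-size sweeps use `delta ∈ {0, 0.5, 1, 2}`. All randomness flows
from a single integer seed per experiment (fold assignment, per-subject
simulation seeds, inner-CV folds), artifacts contain no timestamps, and
a rerun with an identical configuration reproduces every output byte
for byte.

## Known limitations

* The feature bank is count-conformant with the published grid, not a
  verbatim reproduction of the unpublished operator list.
* The step detector is a generic prominence-based peak picker; no
  equivalence with template-matching detectors is claimed.
* Balanced rate is defined as (sens + spec)/2; alternative definitions
  (e.g. reweighted pooled accuracy) would differ by fractions of a
  point on near-balanced cohorts.
* The simulator's clinical scores are a caricature sufficient for
  plumbing subgroup contrasts, nothing more.
* Single-device, single-rate (50 Hz) data model; no resampling between
  heterogeneous devices.
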