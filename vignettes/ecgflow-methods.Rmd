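---
title: "Methods: ECG processing, delineation and validation in ecgflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG processing, delineation and validation in ecgflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgflow)
```

This vignette is the package's account of its methods: the models and
procedures implemented, the parameters that matter, the synthetic data
the validation rests on, and the numerical and design choices that
were genuinely open. Every number quoted here is computed by the test
suite or by `scripts/acceptance.R`; the vignette states no result the
code does not itself produce.

## 1. Signal model and containers

A recording is a 1-D amplitude series in arbitrary units with a
sampling frequency `fs` attached (`ecg_signal`). All sample indices
the package reports — R peaks, fiducial tables, ground truth — are
0-based, matching the CSV schemas whose index column starts at 0:
index `i` refers to `signal[[i + 1]]`.

Per-beat landmarks live in a fiducial table with columns `Q_Points`,
`R_Peaks`, `S_Points`, `T_Points`, `P_Points`, one row per beat. The
constructor enforces the physiological ordering P < Q < R < S < T
within each row and strictly increasing R indices across rows; readers
reject violating rows with a report rather than silently keeping them.

## 2. Noise suppression

Three software stages run in a configurable order, default
median → band-pass → notch:

* **Median filter** (window 3 samples, odd; boundaries by edge
  replication). A 3-sample window is the smallest that removes
  isolated single-sample impulses — the artifact class the stage
  targets — while moving smooth ECG waves by well under a sample's
  amplitude at 360 Hz. Wider windows start eroding the narrow Q and S
  troughs. Window 1 is the identity; even windows are an error.
* **Band-pass**, 0.5–100 Hz, Butterworth order 2, applied
  forward–backward (`signal::filtfilt`). The passband edges are the
  conventional single-lead monitoring band: 0.5 Hz removes baseline
  wander and other sub-cardiac drift, 100 Hz suppresses high-frequency
  noise while keeping QRS energy. The analytic response model
  `H(f) = 1/(1 + (f/fc)^(2n))` is exposed as `response_magnitude()`
  and is exactly 1/2 at `f = fc` for every order; the realized filter
  is the zero-phase Butterworth because a magnitude model alone is not
  a realizable digital filter, and zero phase is what preserves
  fiducial timing — a one-pass IIR filter would drag every landmark
  later by a frequency-dependent lag.
* **Notch**: Butterworth band-stop, mains ± 2 Hz, order 2, zero-phase.
  Mains means 50 or 60 Hz; the band-stop at 50 Hz leaves a 10 Hz tone
  essentially untouched (the suite verifies ≤ 5% amplitude change by
  an FFT oracle while the 50 Hz tone loses ≥ 90%).

Because `filtfilt` starts from zero state, a DC offset produces a
start-up transient with the ~2 s time constant of the 0.5 Hz edge; DC
removal is therefore asserted in the steady-state interior, not at the
record edges.

## 3. Polarity assessment and correction

Swapped electrodes produce a sign-flipped record, which breaks every
downstream maximum/minimum convention. The package clusters *sample
amplitudes* (1-D) with K-means, k = 5, and compares the extreme
centroids: a correctly oriented lead-II-like signal has its dominant
deflection (R) positive, so `|c_max| > |c_min|`; when the most
negative centroid wins, the verdict is `inverted` and the whole signal
is negated. The evidence ratio `|c_min|/|c_max|` makes the rule
antisymmetric: negating the signal takes the ratio to its reciprocal.

Numerical choices: amplitudes are min-max scaled to [−1, 1] before
clustering (K-means on raw units is scale-sensitive) and centroids are
inverse-mapped to original units afterwards, so the polarity rule
operates in physical units; initialisation is k-means++ under a fixed
seed with ties broken by the lowest index; Lloyd iterations are capped
at 300; a constant signal has no polarity and is a degenerate-input
error, as is `k` exceeding the number of distinct amplitudes. The
choice k = 5 mirrors the amplitude strata of a beat (R peak, Q/S
troughs, P/T band, baseline); the polarity verdict itself only uses
the two extreme centroids and is insensitive to moderate changes
in k.

The correction is applied globally (the whole record is re-oriented),
not per cluster: inversion is a property of the electrode montage, not
of individual amplitude strata.

## 4. PQRST delineation

R peaks first: candidates are strict local maxima above an adaptive
threshold, `threshold_factor` (default 1.2) times the rolling 95th
percentile of the signal in a ±1 s window (evaluated on a half-second
grid and interpolated). Candidates are then accepted in order of
decreasing amplitude — ties to the earlier index — subject to a
refractory spacing `min_rr` (default 0.2 s). The refractory rule is
what rejects T waves and P waves as R candidates: with the default
morphology both lie within 0.2 s of their R peak. The detector is
deliberately simple and deterministic; it assumes a polarity-corrected,
band-passed input, and the interface accepts any alternative peak list.

Around each R peak the remaining landmarks are window extrema:

| point | window | extremum | duration | samples at 360 Hz |
|---|---|---|---|---|
| Q | [R − q_win, R) | min | 0.04 s | 14.4 → 14 |
| S | (R, R + s_win] | min | 0.08 s | 28.8 → 28 |
| T | (S, S + t_win] | max | 0.2 s | 72 |
| P | [Q − p_far, Q − p_near] | max | 0.12–0.2 s before Q | 43–72 |

Q and S are window *minima* (the QRS flanking troughs); T and P are
maxima. Fractional window lengths are floored — 14.4 becomes 14 —
which matches the constant R − Q = 14 and S − R = 28 differences
visible in the labelled-beat worked example shipped in
`inst/extdata/table3_labels.csv`. Ties inside a window resolve to the
first extremum. Beats whose windows would cross the record boundary or
run into the next beat's R peak are dropped with a warning and
counted, never emitted half-delineated. Detection is equivariant to
positive amplitude scaling, since both the threshold and the extrema
scale together.

## 5. Isolation Forest beat anomalies

The forest is implemented in the package: 100 trees, per-tree
subsample ψ = min(256, n), split feature uniform among features with
non-zero range in the node, split value uniform in the feature's node
range, growth capped at ⌈log2 ψ⌉. A point's score is
`s = 2^(−E[h]/c(ψ))` with `c(·)` the expected unsuccessful-search
depth of a binary search tree. The automatic contamination policy
declares a row anomalous when `s > 0.5` — the standard score offset —
rather than fitting a quantile to a user-supplied outlier fraction.
The fixed random state (42) makes subsampling and splits reproducible;
repeated calls on the same table return identical labels.

Two feature modes exist. The default `"raw"` mode feeds the five
index columns exactly as tabulated, matching the labelled-beat schema.
Raw indices, however, grow with recording time, so whole-record
position dominates the geometry: a row can look "anomalous" merely for
being early. This confound cannot be resolved from the schema itself,
so the module also offers `"intervals"` — PQ, QR, RS, ST durations
plus the RR interval to the previous beat (first row imputed with the
median RR) — which is position-free. The validation suite uses the
interval mode, because its ground-truth construction (whole-row index
shifts, i.e. rhythm breaks) is numerically invisible to raw columns at
desk scale while leaving all intra-beat durations intact.

On small tables the 0.5 offset is conservative: singleton leaves at
the depth cap already score slightly above 0.5, so a fraction of
unremarkable rows is flagged (the acceptance run reports the measured
false-positive rate alongside the true-positive rate). Accuracy-style
evaluation treats the anomalous label as the positive class.

## 6. Risk-model comparison

Patient tables follow the ten-column schema (Age, Sex, Chest Pain,
Blood Pressure, Cholesterol, Alcohol, Diabetes, ECG Change, Smoking,
Condition), validated on load: binary columns in {0, 1}, positive
continuous columns, no missing values.

The comparison protocol is repeated stratified random splits, default
50 repeats at 80/20 — on 100-to-300-row tables single splits are far
too noisy for a stable ranking, and 50 repeats brings the standard
error of a mean accuracy below about 1.5 percentage points. Feature
scaling (z-scores) is fitted on the training split only and applied to
the held-out fold; the suite tests that held-out rows cannot influence
the scaler. A split whose test fold is single-class is resampled with
a warning. F1 uses condition 1 as the positive class; the degenerate
case (no positives present and none predicted) is reported as 0 with a
warning rather than NA, so aggregates stay defined.

The six families and their implementations: logistic regression
(`stats::glm`), decision tree (`rpart`), random forest
(`randomForest`, 200 trees), RBF-SVM (`e1071::svm` on pre-scaled
features), gradient-boosted trees (`xgboost`, 60 rounds, depth 3,
learning rate 0.3), and a 1-D CNN. No deep-learning framework is a
package dependency: the CNN is a minimal convolutional network written
in the package — kernel 3 over the ordered 9-feature vector, 16
filters, ReLU, dense sigmoid head — trained full-batch with Adam
(learning rate 0.01, 200 epochs), seeded so fits are bit-reproducible.
It trains in well under a second per split on one CPU; the model
interface allows substituting any other classifier.

## 7. What the synthetic generators emulate — and what they do not

**ECG generator.** One beat is a sum of five Gaussian bumps with a
conventional lead-II-like shape: amplitudes (a.u.)
P 0.20, Q −0.10, R 1.00, S −0.25, T 0.25 (R the global extremum,
T > P, Q/S negative); widths (s) 0.025, 0.010, 0.012, 0.010, 0.045;
centers (s, relative to R) −0.19, −0.035, 0, 0.035, +0.19. Beat-to-beat
RR jitter is uniform ±2% by default (switchable off) to avoid
degenerate perfect periodicity. Contamination sources map one-to-one
onto the filter stages: white noise (sd 0.03), baseline wander
(0.1 a.u. at 0.25 Hz), mains (0.02 a.u. at 50 Hz), isolated
single-sample impulses (0.5/s, ±0.5 a.u., Poisson-thinned) — levels
chosen once as realistic wearable-grade contamination relative to a
unit R peak. Global inversion negates the finished record, so the
inverted and non-inverted renderings of one seed are exact sample-wise
negatives.

At short cycle lengths the T-wave center is rate-adapted,
`t_off = min(0.19 s, RR − 0.30 s)` (floored just above the S wave),
with the T width shrunk proportionally — the synthetic analogue of QT
shortening at speed. Without it, the previous beat's T wave would sit
inside the next beat's fixed P-search window somewhere in the
120–170 bpm range, and no windowed delineator of this family could
recover P there. Wave centers are snapped to the sample grid, so with
all noise at zero the true R index is exactly the per-beat argmax of
the rendered samples; ground truth contains every fully contained
beat.

What it does **not** emulate: physiologically detailed dynamics (no
restitution, no respiratory sinus arrhythmia), arrhythmia-specific
morphologies (AF, PVC), electrode-motion transients longer than one
sample, or amplitude drift between beats. Passing the recovery suite
therefore demonstrates correctness of the windowed algorithm under its
own assumptions — clean-to-moderately-noisy, near-periodic,
R-dominant single-lead signals — not clinical-grade delineation of
pathological rhythms.

**Cohort generator.** Binary risk factors are independent Bernoulli
draws at configured rates; ages are uniform over the configured range
(the marginal summaries available give only a range, and a uniform
makes no extra assumptions); blood pressure and cholesterol are
truncated normals whose *truncated* means hit their targets exactly —
the latent mean is solved with `uniroot`, because with asymmetric
bounds a naive truncation would bias the mean upward by about 1 mmHg,
more than the 3-sigma band at n = 10 000. The default marginals
reproduce a 132-participant cardiology-cohort profile (98 M / 34 F,
ages 28–68, mean BP 129.93 mmHg in [94, 200], cholesterol in
[126, 341], 43.18% alcohol, 31.06% diabetes, 55.30% smoking, 37.12%
ECG change); rates not reported for that cohort (chest pain 0.55; BP
sd 15 mmHg; cholesterol mean 233, sd 40 mg/dL) use conventional
clinic values.

The condition outcome uses a logistic link on standardized age, blood
pressure and cholesterol plus the binary factors, with fixed
documented coefficients (age 0.8, ECG change 0.8, blood pressure 0.7,
diabetes 0.7, chest pain 0.6, cholesterol 0.6, smoking 0.5, sex 0.3,
alcohol 0.3) and an intercept centring prevalence near one half. The
coefficients are stylised — chosen so every factor contributes signal
in the conventional direction — not fitted to any real cohort.
`link = "threshold"` instead assigns the deterministic sign of the
score and redraws rows within ±`margin` of the boundary. The margin
default is 2.5 score units, about 1.8 standard deviations of the score
on either side: the class gap must be wide enough that axis-aligned
single trees, not just margin-based learners, can tile an oblique
linear boundary — a narrow band (below about one score sd) leaves a
single tree well short of the 0.95 control level that separability is
meant to guarantee, which would make the positive control test a test
of tree expressiveness rather than of the evaluation harness.

**Outlier injection.** `inject_fiducial_outliers` shifts whole rows
by ± a given magnitude (all five columns together), preserving
intra-beat ordering while breaking the beat-to-beat rhythm — the same
signature as anomalies that appear "early" relative to the
surrounding rhythm. Unperturbed rows are bit-identical, and the
returned index set is the exact ground truth for scoring.

## 8. Problem sizes and tolerances

The validation suite uses: 10–20 s records for filter and delineation
tests; a 40–180 bpm grid at 20 s per rate with a ±3-sample recovery
tolerance (the generator itself quantises true centers to the grid, so
±1 is typical and ±3 allows for trough asymmetry induced by
overlapping waves); 100 seeded 10 s records (half inverted) for the
polarity criterion with a ≥ 99/100 pass level; twenty 50-row tables
with 1–5 injected outliers at 10× the RR spread for the anomaly
criterion (TPR ≥ 0.9, monotone in magnitude); 300-row cohorts with 6
and 10 split repeats for the model-comparison criteria. These sizes
give stable pass/fail behaviour across seeds while keeping the whole
suite under a minute of CPU; `scripts/acceptance.R` re-runs the same
computations from scratch with sub-seeds derived from a single
`--seed`.

## 9. Known limitations

* The R-peak detector is threshold-based and tuned for filtered,
  polarity-corrected signals; heavy baseline wander that survives
  filtering, or rates outside 40–180 bpm, degrade it. It is pluggable
  by design.
* The windowed delineation assumes near-normal conduction intervals;
  it has no notion of biphasic T waves, absent P waves, or bundle
  branch morphologies.
* The fixed 0.5 anomaly-score offset is conservative on small tables
  (singleton leaves at the depth cap score just above 0.5); users who
  need a calibrated false-positive rate should threshold the returned
  scores themselves.
* Raw-index anomaly features confound beat position with beat
  morphology; the interval mode exists precisely because of this, and
  comparisons between the two modes on the same table are informative.
* The WFDB reader covers formats 16 and 212, single- and multi-channel,
  which is sufficient for common public single-lead records but not
  the full format zoo.
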