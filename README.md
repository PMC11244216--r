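# ecgflow

Single-lead ECG processing for wearable-grade recordings: noise
suppression, automatic polarity correction, P/Q/R/S/T fiducial
delineation, Isolation Forest labelling of anomalous beats, and a
tabular cardiovascular-risk model comparison — with seeded synthetic
generators so that every stage can be validated against known ground
truth, without recording hardware or access to clinical data.

## Who this is for

Biomedical-signal engineers and data scientists who need a tested,
reproducible software pipeline for single-lead ECG at wearable sampling
rates (fs = 360 Hz by default), and who want the detection stages
scored against signals whose true beat landmarks are known by
construction.

## What it computes

**Noise suppression.** Three software stages, in configurable order
(default: median → band-pass → notch):

* a running-median filter (window 3) for isolated impulse artifacts;
* a zero-phase Butterworth band-pass, 0.5–100 Hz at order 2, applied
  forward–backward so fiducial timing is never skewed. The analytic
  magnitude-response model is
  `H(f) = 1 / (1 + (f/fc)^(2n))`,
  which equals 1 at DC and exactly 1/2 at the cut-off `fc` for every
  order `n` (`response_magnitude()`);
* a Butterworth band-stop notch at the mains frequency (50 or 60 Hz).

**Polarity correction.** Sample amplitudes are clustered with K-means
(k = 5, k-means++ seeding, Lloyd iterations). A recording is judged
inverted when the most negative centroid exceeds the most positive one
in magnitude, and is then corrected by global negation
`ECG_corrected[i] = -1 × ECG[i]`.

**PQRST delineation.** R peaks are local maxima above an adaptive
threshold (1.2 × rolling 95th percentile) with a 0.2 s refractory
rule. Around each R peak: Q = argmin over [R − 0.04 s, R),
S = argmin over (R, R + 0.08 s], T = argmax over (S, S + 0.2 s],
P = argmax over [Q − 0.2 s, Q − 0.12 s]. At 360 Hz those windows are
14.4, 28.8 and 72 samples (floored when materialised). Output follows
the labelled-beat CSV schema (`Q_Points`, `R_Peaks`, `S_Points`,
`T_Points`, `P_Points`; 0-based sample indices).

**Beat anomaly detection.** An Isolation Forest (100 trees,
subsample 256, random state 42, implemented in the package) scores
each beat row; with the automatic contamination policy a row is
anomalous when its isolation score exceeds 0.5. Labels are +1
(normal) / −1 (anomalous); `summarize_by_label()` reports per-label
column means and `evaluate_against_truth()` scores labels against a
known outlier set.

**Risk models.** For ten-column patient tables (Age, Sex, Chest Pain,
Blood Pressure, Cholesterol, Alcohol, Diabetes, ECG Change, Smoking,
Condition): z-score feature scaling fitted on training folds only,
Pearson correlation matrices, grouped boxplot summaries, and a
comparison of six classifier families — logistic regression, decision
tree, random forest, RBF-SVM, gradient-boosted trees, and a small 1-D
CNN — over repeated stratified train/test splits, reporting accuracy
and F1.

**Synthetic generators.** `generate_ecg()` renders seeded multi-beat
records (sum-of-Gaussian beat morphology, RR jitter, baseline wander,
mains interference, white noise, impulses, optional global inversion)
together with the true sample index of every wave of every beat.
`generate_patient_table()` draws cohorts with configurable marginal
rates and a documented logistic (or separable threshold) link for the
outcome.

## Worked example

```r
library(ecgflow)

# a 30 s inverted wearable-style record with known ground truth
g <- generate_ecg(synth_config(duration = 30, heart_rate = 72,
                               inverted = TRUE, seed = 42))
clean <- preprocess_signal(g$signal)      # median -> band-pass -> notch
fx <- fix_polarity(clean)                 # cluster, assess, correct
fx$verdict
#> <polarity_verdict> inverted (evidence ratio 3.814)

fid <- detect_fiducials(fx$signal, detect_r_peaks(fx$signal))
head(as.data.frame(fid), 3)
#>   Q_Points R_Peaks S_Points T_Points P_Points
#> 1       98     112      126      183       44
#> 2      403     417      430      495      351
#> 3      709     722      735      793      652
```

The verdict shows the inversion was caught (the most negative centroid
was 3.8 times the most positive one); after correction the delineated
rows satisfy P < Q < R < S < T with R − Q ≤ 14 and S − R ≤ 28 samples.

```r
# plant three rhythm breaks in a 50-beat table and ask the forest
inj <- inject_fiducial_outliers(fid[1:50, ], k = 3,
                                magnitude = 10 * sd(diff(fid$R_Peaks[1:50])),
                                seed = 7)
lab <- fit_predict_anomalies(inj$table, anomaly_spec(features = "intervals"))
unlist(evaluate_against_truth(lab, inj$outliers)[c("accuracy", "tpr", "fpr")])
#> accuracy      tpr      fpr
#> 0.800000 1.000000 0.212766
```

All three injected outliers are recovered (TPR 1.0); the automatic
score threshold also flags some beats whose RR spacing fluctuates at
the noise level, which is the conservative side of the auto policy.

```r
cohort <- generate_patient_table(132, seed = 42)   # study-scale cohort
evaluate_models(cohort, repeats = 10, seed = 1)
#> <risk_report> 6 models x 10 stratified splits (test fraction 0.2)
#>          model mean_accuracy sd_accuracy mean_f1  sd_f1
#>       logistic        0.6889      0.0703  0.7025 0.0682
#>  decision_tree        0.6741      0.0953  0.6751 0.1056
#>  random_forest        0.6519      0.1021  0.6606 0.1333
#>            svm        0.6815      0.0959  0.6761 0.1154
#>        xgboost        0.6704      0.0947  0.6837 0.1129
#>            cnn        0.6630      0.0790  0.6775 0.0929
```

On a 132-row cohort with a stochastic logistic outcome, all six
families land in the 0.65–0.70 accuracy band — the irreducible noise
of the link dominates. On a separable cohort
(`link = "threshold"`) every family exceeds 0.95 (see the acceptance
script).

A command-line wrapper is installed with the package
(`inst/exec/ecgflow`): `ecgflow simulate ecg|cohort ...` and
`ecgflow run --config config.yaml`, with exit codes 0/1/2 for
success / validation error / runtime error.

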