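---
title: "audiodx: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{audiodx: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`audiodx` implements a complete diagnostic pipeline for tinnitus from
extended high-frequency audiometry (0.25–16 kHz): synthesizing labeled
threshold profiles, rendering and re-digitizing audiogram charts, imputing
missing entries, extracting three per-ear features, and classifying ears
with logistic regression, a small neural network and a majority-class
baseline. This vignette records the models, the tunable parameters that
matter, and the choices made where the design was genuinely open.

## The synthetic cohort: a stated world

No public dataset of clinical extended high-frequency audiograms exists, so
the package's claims are made against a simulator with known ground truth.
`cohort_config()` defaults to 242 tinnitus and 267 control audiograms (509
subjects, 1,018 ears) on the grid 250, 500, 1000, 2000, 4000, 8000, 10000,
12500, 14000, 16000 Hz.

The generative model per ear, in dB HL:

* a shared age-like baseline: flat at `control_mean_db` (10 dB), rising
  linearly in log-frequency by `age_tilt_db` (5 dB) from 8 kHz to 16 kHz;
* Gaussian per-frequency noise, sd `control_sd_db` (5 dB);
* for tinnitus-labeled ears, at frequencies ≥ 8 kHz: a per-ear severity
  intercept drawn from N(0, `tinnitus_severity_sd_db` = 8 dB), a mean
  elevation, extra per-frequency dispersion (`tinnitus_extra_sd_db` = 5 dB),
  and with probability `notch_probability` (0.3) one notch point elevated by
  `notch_depth_db` (20 dB);
* rounding to the clinical 5 dB step and clipping to \[−10, 120\].

Two structural choices deserve note. First, the per-point elevation is
`tinnitus_hf_shift_db` *minus the expected notch contribution*
(`notch_probability × notch_depth_db / n_HF`), so the realized group
difference in band means equals `tinnitus_hf_shift_db` (20 dB) exactly;
this makes the generator's own effect size recoverable, which the test
suite verifies by Monte Carlo. Second, the tinnitus dispersion is split
into a between-ear severity component and a within-ear component: the
severity intercept creates mildly affected ears that overlap the control
range, which is what keeps classification imperfect and realistic rather
than trivially separable. These magnitudes are choices, not estimates —
the clinical literature motivates the shape (elevated, more variable
high-frequency thresholds, frequent points above 30 dB) but quantifies no
distribution. What a green test establishes is therefore that the
*pipeline* behaves correctly on a world with these contrasts, not that the
clinical effect size is 20 dB.

Missingness is injected completely at random (MCAR) at `missing_rate`
(default 5%) on threshold entries only; labels and identifiers are never
blanked. Real clinical missingness is unlikely to be MCAR; no sensitivity
analysis to informative missingness is attempted.

The generator does **not** model test–retest reliability, age/sex
covariates, masking rules, conductive pathology, or asymmetric hearing
loss beyond the optional unilateral-tinnitus switch.

## Chart rendering and its ground truth

`render_chart()` draws both ears of a subject on one grayscale image
(matrix in \[0, 1\], origin top-left): log-spaced frequency rulings, 10 dB
level rulings, an axis frame, and one glyph per non-missing threshold —
circle for right-ear air conduction, X for left-ear air, chevrons for bone.
dB HL increases downward, the audiometric convention. Placement jitter
(±1 px) emulates imperfect chart production. The truth sidecar records
each glyph's class, jittered center and audiometric coordinates; the
calibration object stores two anchors per axis, which is exactly the
"internal scale" the digitizer later uses. Air and bone glyphs at equal
thresholds overlap by construction, and so do left and right glyphs when
the two ears share a threshold — with 5 dB quantization this is common,
and it is the central nuisance the detection stage must survive.

Because the environment has no binary image I/O, images are exported as
plain-text PGM (P2); in-memory everything is a numeric matrix.

## Symbol detection

Detectors follow the cascade-of-boosted-rectangle-features design:
Haar-like contrasts (two-, three-rectangle, checkerboard and
center-surround types) evaluated in constant time on an integral image;
AdaBoost decision stumps; stages with rejection thresholds set to keep
≥ 99.5% of training positives; and hard-negative mining between stages,
which scans training charts with the partial cascade and feeds its false
positives (grid crossings, axis corners, borders) back as negatives. One
detector is trained per symbol class, and the opposite ear's symbols are
the most important negatives — shift-augmented to a one-pixel stencil.

Two empirical facts shaped the final design:

* **Rectangle contrasts separate glyph classes weakly at 9 px.** The
  cascade drives structural false positives to zero but plateaus near
  8–12% false accepts on opposite-ear glyph patches. The held-out training
  gate (`min_hit_rate` 0.9, `max_false_accept` 0.15) is set with that
  plateau in mind; demanding patch-level cross-class perfection from the
  cascade alone made training fail sporadically without improving final
  accuracy.
* **Overlapping symbols forbid hard template gates.** Roughly a third of
  rendered symbols share their pixel box with the other ear's glyph, so
  any verification that penalizes "extra ink" rejects genuine symbols.
  Cross-class disambiguation therefore happens at digitization as a
  *ranking*: each candidate's glyph-skeleton containment under its own
  detector's template minus the best rival template. For a lone X the
  margin is positive under the X detector and negative under the circle
  detector; for a true overlap both margins are ≈ 0 and both detections
  are (correctly) kept.

Detection is single-scale by default (the renderer controls symbol size),
deterministic row-major, stride 1. Non-maximum suppression is greedy by
score with IoU threshold 0.3, ties broken by smaller x then y; boxes of
different classes never suppress each other. Localization is refined in
two steps — the centroid of the raw detection cluster, then the centroid
of glyph-ink pixels (darkness > 0.5, which excludes grid lines) — giving
sub-pixel centers.

Detector quality remains somewhat seed-dependent (the feature pool is
random): across seeds the 60-chart round trip recovers 92–99% of symbols.
The property gate — ≥ 95% of symbols within 2.5 dB on 50 clean charts —
is asserted on the fixed test fixture; no printed detection accuracy
exists to compare against.

## Calibration and digitization

Frequency is log-linear in the horizontal pixel, level linear in the
vertical pixel; two anchors per axis define the maps, extrapolation is
flagged. Recovered frequencies snap to the nearest grid frequency in
log10 distance, exact ties to the lower frequency. The 2.5 dB acceptance
tolerance is half the conventional 5 dB audiogram step: an error below it
can never change the recorded clinical value after re-quantization.
Optional 5 dB quantization of recovered levels is off by default.
Duplicate detections on one (grid frequency, class) keep the better
arbitration margin, then the better score.

## Imputation

`mice_impute()` is a from-scratch chained-equations imputer: left-to-right
column visits, initial fill by observed mean (continuous) or majority
(binary), predictive mean matching with k = 5 donors drawn uniformly for
continuous columns, logistic-regression Bernoulli draws for binary
columns, 10 iterations, 5 chains. The model for each column is fit on the
originally observed rows only. PMM guarantees every imputed value is an
observed value of its column.

Classical multiple imputation would analyze each chain separately and pool
by Rubin's rules; this pipeline needs a single completed table, so chains
are pooled per cell (mean for continuous, majority for binary). That
understates between-imputation variance — acceptable here because the
completed table feeds a classifier, not an interval estimate. Counts
(iterations, chains, donors) are conventional defaults; nothing in scope
pins them down.

## Features and classifiers

Per ear, over air-conduction thresholds in the inclusive 8–16 kHz band:
the mean, the sample (n−1) standard deviation, and a strict indicator of
any threshold > 30 dB. At least two usable band points are required; ears
failing that are skipped and logged. Bone conduction is digitized but
never feeds features.

The logistic model minimizes
Σᵢ log(1 + exp(−sᵢ(w·xᵢ + b))) + ‖w‖²/(2C), sᵢ = 2yᵢ − 1, intercept
unpenalized, by damped Newton iterations with a backtracking line search
(monotone objective decrease, zero initialization, deterministic). C is
tuned over {0.01, 0.1, 1, 10, 100} by stratified 5-fold validation AUC;
exact AUC ties go to the smaller C, i.e. the simpler model. On perfectly
separable folds every C reaches AUC 1 and the tie rule returns 0.01.

The network is read as two ReLU hidden layers (32, 16 — widths are ours;
none are reported) and a sigmoid output unit: a sigmoid "hidden" layer
feeding another sigmoid output would be redundant. Training is mini-batch
Adam (0.001, β₁ 0.9, β₂ 0.999, ε 1e−8) on binary cross-entropy, 100
epochs, batch 32, seeded Glorot initialization and shuffling. The
classification threshold is 0.5 everywhere.

In `run_tabular()` standardization uses training-split statistics, also
inside the C grid search (per-fold re-standardization is skipped). The
leakage affects fold AUCs in at most the third decimal here and never the
test-set evaluation; a stricter implementation would re-standardize per
fold. The binary indicator is passed through unscaled — z-scoring a 0/1
column only rescales its coefficient.

## Evaluation

All metrics are computed from scratch and cross-checked in the tests
against brute-force oracles. Class order is fixed (normal, tinnitus);
tinnitus is the positive class for AUC and MCC. The 70/30 split rounds
per-class test counts with a largest-remainder correction to the global
target (1,018 ears → 305 test ears). AUC is the rank statistic with
half-credit for ties, so a constant-score classifier scores exactly 0.5.
Zero denominators in precision/recall/F1, kappa or MCC yield 0 with an
explicit flag. Reports print at two decimals; JSON artifacts keep full
precision.

## Determinism and numerics

Every stochastic stage takes a seed; a single run seed is expanded into
independent per-stage streams by a string-keyed hash, so adding a stage
never shifts another stage's draws. Reruns with equal seeds produce
byte-identical artifacts (model JSON uses 17 significant digits, which
round-trips doubles exactly — with fewer digits a deserialized cascade
can vote differently at threshold-boundary windows). Degenerate inputs
are errors with classed conditions: all-missing columns, one-class AUC
inputs, out-of-axis thresholds, invalid IoU thresholds, unmeetable
detector targets (reported with achieved rates).

## Known limitations

* The synthetic world is Gaussian around a smooth baseline; real
  audiograms have configuration shapes (noise notches, ski slopes) only
  crudely captured by the single-notch mechanism.
* The renderer draws one chart style; the detectors are not expected to
  transfer across styles without retraining, and no automatic axis
  detection is attempted — external images need a user-supplied anchor
  file.
* Patch-level cross-class false accepts are inherent to small-window
  rectangle features; precision relies on the digitization-stage
  arbitration described above.
* MCAR missingness and mean/majority pooling understate imputation
  uncertainty.
* Absolute classifier accuracies on the synthetic cohort measure the
  stated world's separability, not clinical performance.
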