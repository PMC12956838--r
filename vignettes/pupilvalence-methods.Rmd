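---
title: "Classifying emotional valence from pupil dynamics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying emotional valence from pupil dynamics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(pupilvalence)
```

## The problem

Whether pupil size carries information about the *valence* of an
emotional stimulus — positive versus negative — has been contested for
decades, largely because pupil dynamics are dominated by low-level
visual properties (luminance, spatial frequency) and by emotional
arousal. `pupilvalence` implements a complete analysis pipeline for the
question: rule-based cleaning of pupil-diameter time series, a
45-feature summary of the constriction-then-recovery waveform,
quantification and binning of stimulus visual properties, exploratory
dynamic-time-warping clustering, and a leakage-safe classification
harness that compares an *uncontrolled* pooled analysis against
analyses *stratified* by arousal level and spatial-frequency (SF)
level. The human dataset such a study would use is not distributable,
so the package ships a first-class synthetic-data generator that
reproduces the statistical structure the analysis assumes; every stage
of the pipeline is tested against it.

## Data model and conventions

A trial is 6 s of monocular pupil diameter at 60 fps — 360 frames.
Raw diameters (device units) are normalized to a per-participant
baseline fixed at 100, giving the dimensionless relative pupil size
`D_RATIO = 100 * value / baseline`. The baseline is an *input* (a
scalar column in the trials CSV): how a lab derives it (pre-stimulus
gray-screen mean, session mean, ...) varies between setups, and
guessing a convention here would silently change every downstream
number. Frames are 1-based everywhere: frame 1 is stimulus onset,
latencies are reported in frames, and serialized files say so in a
header comment.

## Cleaning rules

Cleaning is deliberately rule-based and order-sensitive, applied per
trial in this sequence:

1. **Jump rule.** Scanning frames in order with a reference `r` equal
   to the last *accepted* frame's value: a frame deviating from `r` by
   more than 10% opens a missing interval; frames stay missing until
   the first frame back within 5% of that same reference, which is
   retained and becomes the new reference. Comparing against the last
   accepted frame rather than the immediately preceding (possibly
   artifactual) frame prevents an interval from "closing" in the middle
   of a blink, where consecutive contaminated frames resemble each
   other.
2. **Interpolation.** Missing runs of at most 30 frames — twice the
   ~250 ms minimum latency at which pupil size can track a stimulus at
   60 fps — are filled with PCHIP (shape-preserving piecewise cubic
   Hermite, via `pracma::pchip`), which passes through every anchor and
   cannot overshoot on monotone data. Longer runs exclude the trial.
3. **Range rule.** Frames with `D_RATIO` strictly below 40 or strictly
   above 160 are marked missing (the bounds themselves survive:
   "exceeds" means strict inequality throughout), followed by the same
   interpolate-or-exclude step.

Two further conventions are worth stating. Runs touching the first or
last frame have no anchor on one side; rather than extrapolate a cubic
(unreliable), such trials are excluded. And interpolation runs after
*each* marking stage, so the range rule sees a fully populated trace;
final validity is evaluated after both. Cleaning is idempotent: a trace
that passed is unchanged by a second pass (verified as a property
test).

## The 45 features

The feature set summarizes the stereotyped light-reflex waveform —
rapid constriction to a minimum followed by gradual recovery:

* point statistics: `max`, `min`, `mean`, `std` (population), `start`
  (= frame 1), `finish` (= frame 360);
* waveform descriptors: `peak` (maximum after frame 50, i.e. past the
  initial constriction), `peak_latency`, `drop_latency` (first frame
  attaining the extremum; ties go to the earliest frame),
  `peak_ratio = peak/min`, `drop_ratio = min/start`,
  `recovery_ratio = finish/start`,
  `response_duration = peak_latency - drop_latency` (signed; the peak
  may precede the minimum), `reaction_extent = drop_ratio +
  recovery_ratio`, `stability = mean/std`, `range`,
  `baseline_deviation = start - mean`;
* cumulative features: `aupc`, the area under the pupil curve as the
  plain sum of per-frame `D_RATIO` over the 360 frames (rectangle rule,
  unit spacing — the simplest convention, bit-reproducible, and within
  a negligible boundary term of the trapezoid), plus `aupc1..aupc6`
  over six 60-frame windows; `change_sum`, the total absolute
  frame-to-frame change, plus `change_sum1..6`, where the difference
  crossing a window boundary is assigned to the *later* window so the
  six window sums partition the total exactly;
* `s_`-variants of all cumulative features, computed after rescaling
  the trace so its first frame equals 100 — these are invariant to
  multiplying the whole trace by any positive constant.

The three "compared to" descriptors are ratios (not differences),
chosen uniformly. A zero-variance trace makes `stability` undefined;
such trials are excluded from feature extraction (an error, caught and
logged by the table builder) rather than imputed. Every feature is
checked against an independent straightforward re-implementation on
random traces to 1e-9.

## Stimulus properties

Spatial frequency is scored by a gradient measure: the mean absolute
intensity difference between horizontally adjacent pixels and between
vertically adjacent pixels, averaged over the two directions, on the
0–255 scale. This is the simplest estimator matching a "local intensity
variation" definition; it is zero iff the image is constant, shift
invariant, and linear in contrast. Since its absolute units are
arbitrary, the meaningful output is the SF *level* (1–5): either fixed
boundaries (midpoints of the gaps between the five observed score
ranges of the stimulus set, with out-of-range scores clamped to the
extreme levels) or equal-frequency quintiles of a supplied score set.
Arousal ratings on the 1–7 scale bin as 1–2 low, 3–5 mid, 6–7 high;
ratings 8–9 are outside the stimulus design and rejected. Luminance
normalization is an additive shift to mean 127.5 with clipping (one
corrective re-shift), since only a mean constraint is imposed.

## Synthetic data generator

The generator is the package's testbed and defines its study
conditions: 40 participants × 50 stimuli (25 positive, 25 negative),
360 frames. Each trial is a deterministic template plus structured
noise:

* **Template.** From 100, a half-cosine fall to `100 - C` at frame
  `t_min`, then exponential relaxation toward a plateau `P_end` with
  time constant `tau = 80` frames. This is the fewest-parameter shape
  with the right qualitative anatomy (constriction around frame ~50,
  partial recovery).
* **Valence effects.** Negative stimuli constrict deeper
  (`C`: 21.5 vs 16.5), faster (`t_min`: 46 vs 54 frames), recover less
  (`P_end`: 98.5 vs 103.5) and fluctuate more (AR(1) innovation sd 1.95
  vs 1.45) — the directionality expected if negative valence shows
  rapid constriction, smaller sustained size and less stable traces.
  `valence_effect_size` scales all four contrasts about their
  midpoints; 0 removes the class signal entirely (the null used for
  calibration tests).
* **Visual confounds.** Standardized SF (fixed standardization
  constants: mean 14.27, sd 8.61, the scale of the emulated stimulus
  set) deepens `C` and lowers `P_end` by 4 `D_RATIO` units per SD —
  a sustained-suppression effect, independent of valence. Arousal
  multiplies the deviation from baseline by 1.15 per level. Both are
  assigned independently of valence, so they add label-independent
  variance that stratification can remove — which is exactly the
  phenomenon the stratified grid is meant to demonstrate.
* **Heterogeneity and noise.** Per-participant random effects on depth
  / plateau / latency (sd 3.5 / 3.0 / 5) and trial-level jitter
  (3.0 / 2.5 / 5), AR(1) noise (coefficient 0.8) with a log-normal
  per-trial scale jitter (sigma 0.25) so trace-roughness features carry
  class signal without becoming deterministic class markers.
* **Artifacts.** Poisson blinks (rate 0.7/trial, durations 4–36
  frames, values collapsing to 10–30% of baseline) and single-frame
  spikes (+15–30%), exercising both cleaning rules; durations above 30
  frames produce genuine exclusions (~24% of trials at defaults).

These values were fixed once, at design time, to produce a regime a
pupillometry study of this size could plausibly occupy: a pooled
grouped-CV logistic AUC in the high 0.8s, a genuine (not merely noisy)
improvement from arousal × SF stratification, chance-level performance
under the null, and roughly three-quarters of trials surviving
cleaning. Everything is deterministic given the config: every random
draw is seeded through a context hash (seed + stage + participant +
stimulus), so any single trial can be regenerated in isolation and the
full dataset is byte-identical across runs.

What the generator does **not** emulate: gaze-dependent foreshortening,
luminance transients, pupillary hippus beyond AR(1), correlations
between valence and visual properties, or any specific real image
content. Passing tests therefore show that the pipeline recovers the
signal structure it assumes — not that real data contain that
structure.

## DTW clustering

Exploratory clustering of the 50 stimulus-averaged curves uses k-means
(k = 6) under dynamic time warping. Conventions, since they are
unstated in most descriptions: local cost is the squared pointwise
difference with a final square root, unconstrained paths with unit
steps, computed by dynamic programming (Rcpp; the distance is verified
exactly against brute-force enumeration of all monotone warping paths
on short sequences). Centroids update by DTW barycenter averaging
capped at 10 inner iterations; each update keeps the best of {previous
centroid, barycenter, medoid} under the within-cluster cost, so the
objective is provably non-increasing. Initialization draws k distinct
curves by seeded sampling with stimulus-id tie-breaking; empty clusters
are reseeded with the worst-fitted curve. Output clusters are
renumbered in ascending order of centroid mean pupil size, so cluster 1
is always the most constricted. Clustering is exploratory only — its
outputs never feed classification.

## Classification harness

All model evaluation uses participant-grouped k-fold cross-validation
(k in {3, 5, 7}): participants are shuffled by seed and partitioned, so
no participant contributes to both sides of a split. SMOTE, when
enabled, runs strictly inside each training fold: synthetic minority
samples are `x + u (x_nn - x)` with `x_nn` one of the k nearest
minority neighbors (k in 1–5; small k keeps interpolation local when
the minority is small) and `u ~ U(0, 1)`; every output row carries
provenance (source and neighbor row indices), which the tests use to
prove no synthetic sample derives from a held-out row.

The roster has eleven classifiers: logistic regression, RBF-kernel SVM,
decision tree, random forest, 5-NN, depth-wise gradient boosting
(xgboost), leaf-wise histogram gradient boosting (the LightGBM
tree-growth algorithm, run via xgboost's `lossguide` policy under the
`lightgbm` identifier), bagged trees, easy ensemble (balanced
undersampling bags of AdaBoost.M1 with shallow rpart learners),
balanced random forest (per-tree balanced bootstrap), and RUSBoost
(AdaBoost with per-round random undersampling). All use standard
defaults — no hyperparameter search anywhere, since per-cell sample
sizes would make a search an overfitting engine. Logistic, SVM and k-NN
see train-fitted z-scored features; tree ensembles see raw features.

Metrics: accuracy, precision, recall, specificity, F1, AUC (the
Mann–Whitney rank statistic, ties counted 1/2 — cross-checked against
pROC in tests) and the P4 score, the harmonic mean of precision,
recall, specificity and NPV — a conservative scalar that is symmetric
under class swap and collapses to 0 if any of the four rates degenerates.
Undefined ratios (zero denominators, which genuinely occur in small
stratified cells) are reported as 0 with a flag, never dropped, so fold
averages stay totals over all folds. Positive valence is the positive
class throughout. Mean ROC curves average fold-wise TPR at 101 evenly
spaced FPR points with endpoints pinned at (0,0) and (1,1).

The stratified grid runs every requested classifier × SMOTE-k × fold
count inside each (arousal level × SF level) cell, requiring at least
`cv_folds` samples of each class (and as many participants as folds);
smaller or single-class cells are reported absent rather than imputed.
Because different summaries of such a grid legitimately use different
winners, the best configuration per cell is recorded twice — by mean
AUC and by mean P4 — and both tables are emitted.

Feature attribution for the logistic model uses the exact closed form
for linear models under feature independence: the contribution of
feature j in sample i is `beta_j (x_ij - mean(x_j))` on standardized
inputs, and features rank by mean absolute contribution. For non-linear
families a seeded permutation importance (AUC drop on held-out
participants) is provided and labeled as such.

## Problem sizes and runtime choices

The test suite and the analysis scripts run the full design (2000
trials of 360 frames) for the end-to-end recovery, null-calibration and
clustering checks, and small constructed instances everywhere else
(sequences of length ≤ 8 for the DTW oracle, 100-trace batches for the
feature oracle, 12–40 participants for fold-plan properties). The
stratified grid in the scripted analysis uses three representative
classifiers; the full roster times eleven models times six SMOTE
settings times three fold counts is available but is a
several-CPU-hour computation and adds nothing methodological.

## Known limitations

* The cleaning rules' reference conventions (jump rule measured against
  the last accepted frame; strict thresholds; two-pass interpolation)
  are one defensible reading of a procedure that is usually described
  only loosely; all are isolated behind the `preprocess` functions and
  covered by example-level tests, so a lab with different conventions
  can swap them.
* The SF score's absolute scale is arbitrary; only level assignment is
  interpreted.
* DTW k-means is a local optimizer; with a different seed the partition
  can differ. The renumbering convention makes reports comparable, not
  the partition itself.
* The generator's parameters are free choices for testability, not
  estimates from human data; none of the package's synthetic results
  are claims about real pupillometry beyond the directionality built
  into the design.
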