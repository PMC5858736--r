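---
title: "Detecting sequential context effects in reader studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sequential context effects in reader studies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanseq)
```

## The problem

When a radiologist reads a long sequence of screening mammograms, each case is
pathologically independent of the last — but the reader is not. Judgments in
sequential perceptual tasks are known to drift toward features of, and
decisions about, the preceding stimuli (the *sequential context effect*).
`scanseq` is a pipeline for detecting and quantifying that effect in reader
studies: it quantifies visual search by the fractal dimension (FD) of the gaze
scanpath, pairs each decision with the behavior, decisions and case properties
of up to five preceding cases, and asks — via autocorrelation, fixed-effects
ANOVA and within-reader leave-one-case-out prediction — whether the past
predicts the present decision.

Because raw human eye-tracking data from such studies are generally not
shareable, the package includes a first-class synthetic study generator with
an *injectable* context bias, so the whole pipeline can be exercised and
calibrated end to end: a method that claims to detect sequential dependence
must light up when bias is injected and stay quiet when it is not.

## The reference study design

The emulated protocol: 100 four-view screening cases (50% malignant, the rest
split evenly between benign and normal; BI-RADS parenchymal density 1–4), read
independently by 10 readers in three experience tiers (3 new trainees N, 4
advanced trainees A, 3 experts E), each in an individually randomized order,
optionally across multiple sessions, with gaze sampled at 60 Hz across two
side-by-side displays. Reported ratings come from
`{none, 2, 3, 4A, 4B, 4C, 5}` and collapse to pathology groups
N = {none}, B = {2, 3}, M = {4A, 4B, 4C, 5}; densities collapse to
fatty / fibroglandular / heterogeneous-dense (3 and 4 merged — dense cases are
scarce).

## Synthetic-data model

`generate_study()` draws one shared case set by exact largest-remainder
quotas (so a 100-case set has *exactly* 50/25/25 cases, not approximately) and
gives each reader an independent permutation. Defaults we had to choose
ourselves, once:

* **Density weights** 0.10/0.40/0.40/0.10 over grades 1–4 — approximate
  screening-population frequencies; the reference protocol states only the
  range 1–4.
* **Accuracy by tier** N = 0.55, A = 0.65, E = 0.75 — the reference study
  reports no per-reader accuracy; any convention with N < A < E serves, since
  no acceptance check depends on the absolute values.
* **Viewing time** lognormal around a 20 s mean (tests and the acceptance
  script pass shorter durations purely for runtime; the 60 Hz rate is fixed
  by the protocol).

**Decisions.** With probability `1 - bias_alpha` the reader draws from a base
model: the true pathology group with probability `accuracy`, otherwise one of
the other two groups uniformly; then a rating uniform within the group's
rating set. With probability `bias_alpha` the reader repeats the *previous
decision's group* instead. The bias acts at the group level, not the raw
rating level, which keeps the mechanism identifiable by the grouped analyses
downstream. Session breaks reset the chain (the first case of a segment has
no previous decision).

**Scanpaths.** A fixation–saccade random walk: fixation count is Poisson with
mean `3 + 45·complexity`; centers are uniform over a central active region
whose extent grows with complexity; dwell jitter is Gaussian
(`sd = 4 + 26·complexity` px); saccades are 3-sample straight-line
transitions. The `complexity` knob (derived by default from case density via
`complexity_gain`) is *defined* by its contract: FD must increase with it on
average, and it does (Spearman ≈ 0.9 over 200 scanpaths; the tested bound is
≥ 0.5). This generator emulates none of the physiology of eye movements — no
fixation-duration distributions, no saccadic main sequence, no saliency. A
green test therefore establishes that the *pipeline* recovers injected
structure, not that real radiologists behave like the generator.

**Seeding.** One master seed; every reading, reader and stage draws from a
substream keyed by `substream_seed(seed, ...)`, a stable 31-bit string hash.
Regenerating one reading never shifts another, and studies are byte-identical
across runs given the same configuration.

## Scanpath fractal dimension

The scanpath — time-ordered raw gaze samples connected by line segments — is
rasterized onto a `G × G` occupancy grid (default `G = 512`) and its
Minkowski–Bouligand dimension estimated by box counting: `N(ε)` is the number
of aligned, non-overlapping `ε × ε` blocks containing an occupied cell, and
FD is the OLS slope of `log N(ε)` versus `log(1/ε)`.

Numerical choices, none of which the source analysis pins down, all fixed
here once:

* **Rasterization is conservative (supercover)**: every cell a segment
  touches is occupied, implemented by exact voxel traversal. Classic
  one-cell-per-step Bresenham under-marks steep diagonals and would make the
  occupied set depend on the major axis.
* **Frame and aspect**: one FD per reading over the dual-display global frame
  (display 2 offset by the display-1 width), scaled into the grid with aspect
  preserved (letterboxed). Anisotropic stretch would distort the estimate.
* **Scales** `{2, 4, …, G/4}`: the largest dyadic scales are excluded a
  priori (slopes degenerate when only a handful of boxes remain).
* **Saturation filtering**: among scales with `N(ε) = 1` only the first is
  kept; among scales where `N(ε)` equals the occupied-cell count (no further
  refinement possible) only the coarsest is kept; ≥ 3 usable scales are then
  required. The all-ones curve (a single occupied cell) is the degenerate
  point case and returns FD = 0 exactly.

Because grid size, scale set and fit range are conventions, *absolute* FD
values are convention-dependent; every analysis downstream uses
within-package FD consistently. The estimator is validated against exact
cases (filled grid → 2, point → 0), a rasterized diagonal (→ 1 ± 0.05), and
a Koch polyline at iteration 5 (→ log 4/log 3 ± 0.1), and the box counter
against a brute-force block scan.

## Lag structure and autocorrelation

`build_lag_pairs()` forms, per reader and lag depth `i ∈ 0..5`, rows
`(D0; F0, P0; F1, P1, D1; …; Fi, Pi, Di)` strictly within session segments,
giving `m = Σ_segments max(0, len − i)` rows — for a 100-case reader with `s`
interruptions, `m = 100 − i·(s+1)`, matching the uninterrupted special case
`m = 100 − i`.

`autocorrelation()` is the biased (1/n-normalized) sample ACF with the
white-noise 95% band `±1.96/√n` — the normalization that band is calibrated
for, verified by simulation (band exceedance ≈ 5% on white noise, AR(1)
φ = 0.5 recovered at n = 10⁴). Decision series are analyzed on their ordinal
codes 0–6 (rank order of `{none, 2, 3, 4A, 4B, 4C, 5}`); the source analysis
never states its numeric coding, and rank preserves severity order. A
six-level coding merging `{4C, 5}` is available (`coding = "6"`) because the
source describes both conventions; the seven-level form is the default.

## Fixed-effects ANOVA

`fixed_effects_anova()` regresses the ordinal decision code on any set of
terms over the factor menu F0–F5 (continuous, standardized), P0–P5 (3-level,
treatment-coded) and D1–D5 (categorical), with interaction columns as
elementwise products. Each term is tested by a **partial (drop-one) F test**
against the full model — sequential sums of squares would make the composite,
overlapping terms order-dependent. Treating the ordinal response as numeric
in a linear model is an interpretation (the source states no link function);
the null calibration test confirms the resulting test is exact at the 5%
level when the response is independent normal noise. Degeneracies are
handled explicitly: constant design columns from empty interaction cells are
dropped with a warning (same spirit as merging scarce dense cases); true
rank deficiency raises an error naming the aliased terms; an exactly-fitting
response is guarded so remaining terms report F ≈ 0 rather than NaN.
`preset_table_terms()` ships the menu of composite high-order interactions
from the reference analysis; note that the largest of them are only
estimable on far bigger datasets than 100 cases — a full factorial over all
16 factors is refused by the row/column checks.

## Prediction and scoring

`loocv_predict()` refits once per row (leave-one-case-out), and
`weighted_f_score()` scores held-out predictions by support-weighted per-class
F1. The classifier is a random forest — bagged CART trees, Gini splits,
`√p` features per split, majority vote with ties to the lowest class index —
authored in C++ inside the package because no tree ensemble ships with the
target environment. Defaults (500 trees, unlimited depth, node size 1) are
exposed in `model_spec()`; simulations in tests use 100–200 trees, which is
runtime economy, not tuning. Categorical features are one-hot encoded; FD
enters raw (trees are scale-free).

`random_chance_baseline()` is **marginal** guessing — predictions drawn from
the empirical label distribution — rather than uniform guessing: observed
per-reader chance baselines vary with label skew, which uniform guessing
cannot produce. It is validated against an exact enumeration oracle at n = 6.

`sweep_lags()` produces the per-reader × per-lag report with per-tier
arithmetic means, mirroring the published table layout
(`format_report_table()`).

## What the acceptance checks establish

The reference study's own per-reader results derive from unreleased human
data and are not reproducible; the package's acceptance suite therefore
combines (a) arithmetic checks on the published per-reader table (tier
averages, the 64% improvement-over-chance figure), (b) analytic and
brute-force oracle checks on the numeric core, and (c) bias recovery: with
`bias_alpha = 0.75` the lag-1 model must beat the lag-0 model and the D1
ANOVA term must be significant in ≥ 80% of replicates, while with
`bias_alpha = 0` improvements must center on zero and D1 significance must
stay at the nominal false-positive rate. Thresholds and replicate counts are
fixed design choices, not tuned quantities.

## Known limitations

* The scanpath generator spans FD ≈ 1.0–1.8 but is not a model of human
  search; effect sizes measured on it do not transfer to real readers.
* The ANOVA treats an ordinal response as interval-scaled; an ordinal-logit
  variant is out of scope.
* High-order preset interaction terms are not estimable at reader-study
  sample sizes; they are provided as specifications, not as recommended
  analyses at n ≈ 100.
* Intermediate clinical cases read between interrupted sessions are not
  modeled; sessions simply restart the lag structure.
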