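---
title: "Methods: KDE feature transforms and MCC-driven model selection for polyp risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KDE feature transforms and MCC-driven model selection for polyp risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(polypkde)
```

This vignette documents the modelling choices behind `polypkde`: the
probabilistic feature transform, the optimization loop, the synthetic
cohort generator, and the numerical conventions. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem and the data model

A record is one health checkup joined to a colonoscopy performed within a
year: sex, age, ~39 continuous labs and ordinal lifestyle codes, a fecal
immunochemical test (FIT) result, and the maximum polyp diameter found at
colonoscopy (0 mm = none; recorded polyps start at 1 mm). Eligibility
removes, in a fixed order, repeat colonoscopies, prior colorectal surgery,
inflammatory bowel disease, FAP/Lynch syndrome, age ≤ 20, and
colonoscopies more than 365 days after the checkup; a record with several
flags is counted at its first matching stage, so stage counts are disjoint
and sum with the eligible count to the input size. Feature-wise discard
limits (e.g. triglycerides > 1000 mg/dL) drop records whose labs indicate
acute illness or entry error rather than screening-relevant state.

Labels come from a polyp-size threshold `t ∈ {0, 6, 8, 10}` mm: positive
iff `max_polyp_mm ≥ max(t, 1)`. Threshold 0 therefore means "any recorded
polyp" — sizes start at 1 mm, so no separate convention is needed. All
modelling is sex-stratified, reflecting the different prevalence and
feature distributions of men and women.

Missing feature values are retained and median-imputed, with medians
learned on the training split only; discarding incomplete records would
disproportionately lose scarce positives.

## The transform

For each feature the polyp-positive training values define a Gaussian KDE,
computed as an exact kernel sum (no binning/FFT shortcut — the grid values
are the package's core primitive and are tested against a brute-force
oracle at 1e-10):

* grid: 512 even points spanning `[min − 3h, max + 3h]`; beyond ±3h the
  Gaussian kernel contributes < 0.5% of its mass, so the density has
  effectively reached zero at the grid ends;
* normalization: to unit **maximum**, not unit area. The transformed value
  is read as "how close this measurement sits to the polyp-typical range",
  so the natural scale is relative density with the mode at exactly 1 for
  every exponent;
* exponent `e ∈ {1..4}` applied after normalization: pointwise
  non-increasing on (0,1], sharpening tails while fixing the mode;
* evaluation at new points by linear interpolation on the grid, clamping
  to the end values outside it (the ends are ≈ 0, or 1 on the saturated
  side of a sigmoid curve).

The sigmoid-like variant clamps all grid values on one side of the density
maximum to 1 — `direction = "higher"` saturates risk at and above the
mode, `"lower"` at and below it — and the exponent is applied after
clamping (clamped values are 1 either way; stated for determinism). For a
unimodal KDE the remaining limb is already monotone; for multimodal fits a
running maximum toward the mode enforces the monotone contract, which is
what makes the curve usable as a saturating risk score. Per-feature
directions come from the schema; `"auto"` resolves by comparing class
medians on training data (positive-class median higher → `"higher"`),
with a config override. HDL defaults to `"lower"`: it is protective, so
low values carry the risk.

Bandwidths default to Silverman's rule on the positive-class values.
`optimize_bandwidth()` tunes them coordinate-wise over Silverman ×
{0.25, 0.5, 1, 2, 4}, maximizing the full model's cross-validated MCC with
the other features' bandwidths held fixed and ties broken toward the
smaller bandwidth (smoother models are preferred only when they pay). A
univariate objective would be cheaper but can prefer bandwidths that help
a feature in isolation and hurt the joint model; the full-model objective
matches the pipeline's single selection criterion. Zero-variance features
are flagged and keep the default.

The transform is strictly per-feature (no joint density), is always fitted
on the positive class of the training split only, and test rows are
transformed but never used for fitting — inside cross-validation the
transform is refit on each fold's training part, so no density information
leaks into held-out folds.

## The optimization loop

The grid enumerates threshold × transform mode (`none`, `kde`,
`sigmoid_kde`) × exponent × classifier. The zoo holds ten
fixed-hyperparameter classifiers: AdaBoost (50 stumps), Bernoulli naive
Bayes, a Gaussian-process classifier (RBF kernel), gradient boosting (100
depth-3 trees, learning rate 0.1), LDA, linear SVC and RBF SVC (cost 1),
ridge-penalized logistic regression and ridge least squares (λ = 1/n), and
a one-hidden-layer perceptron (5 units, decay 0.1). Two conventions
matter:

* **No classifier standardizes its inputs.** Putting features on a common
  (0,1] scale is precisely what the transform contributes; the mode-none
  baseline is deliberately exposed to raw measurement scales, as it is in
  the fixed-default stacks this zoo mirrors. Bernoulli naive Bayes is the
  one deviation from those stacks: it binarizes at training medians rather
  than at zero, because a zero threshold degenerates on all-positive lab
  and probability-like features.
* Both sexes are offered the same (union) zoo; any divergence in which
  classifiers win is then a result, not a configuration choice.

Backward elimination trials each remaining feature's removal by re-running
cross-validation without it and eliminates the feature whose removal
yields the highest CV MCC — the stated "feature that decreases
discrimination most" is ambiguous between retraining and perturbation
readings; leave-one-feature-out retraining is consistent with the MCC
objective and yields a deterministic, strictly nested path. Iteration
stops at 3 features; ties break by schema order. Cross-validation is
stratified 5-fold with a fixed seed inside the training split.

Selection refits the global top 6 candidates by CV MCC (global rather than
per-cell: the final choice is a single model per sex, so candidates
compete across thresholds and transforms) on their full training split and
picks the test-MCC argmax; ties break by higher CV MCC, then zoo order.
The test split (stratified 25% by default; the source protocol does not
state its split) is touched only at this final step. Polyp scores are
class-1 probabilities where the classifier provides them; otherwise the
decision function is min–max scaled by the training-score extremes and
clamped to [0,1]. Binary predictions cut the score at 0.5 (no operating
point is stated by the protocol; 0.5 on a probability-like score is the
neutral choice). MCC of a degenerate confusion matrix (any zero marginal)
is defined as 0.

## Evaluation and attribution

`metrics_report()` returns the confusion counts, sensitivity, specificity,
accuracy, MCC, rank-based AUC (Mann–Whitney, ties at ½), and the confusion
matrix normalized per true-class row. The FIT baseline treats a positive
FIT as a predicted positive against the same thresholded labels; because
the relevant denominator is unstated in the source protocol, it is
reported both on the test split (the models' own denominator) and on all
eligible records. Kruskal–Wallis screening reports per-feature H and raw
p-values, with a Benjamini–Hochberg column emitted for reference but not
used for selection, matching the screening-table convention it mirrors.

Shapley attributions use exact coalition enumeration up to 12 features and
permutation sampling above that, against a background sample of at most
100 training rows; both satisfy the additivity identity (base value + row
sum = model score) by construction. Attribution defaults to explaining the
test split — the importance claim is about generalization, not training
fit. The per-patient report requires a sigmoid-KDE model: "this biomarker
is near 1" is only advice-shaped when the curve is a monotone saturation;
the near-1 flag threshold defaults to 0.9 and is configurable.

## The synthetic generator

Real cohorts of this kind are hospital-owned, so the package generates its
own study conditions. Defaults: 1000 records per sex; polyp prevalence
0.30 (men) / 0.20 (women); polyp sizes from a categorical law over the
1–5 / 6–7 / 8–9 / ≥10 mm bands with probabilities matching the nested
counts of the reference cohort flow (337, 97, 20, 93 of 547), uniform
integer within band; FIT sensitivity 0.30 and specificity 0.90 given polyp
status — a deliberately weak baseline, as stool tests are for adenomas;
ages 40–80; all records eligible. Six informative features — age, BMI,
waist, HDL (negative effect), gamma-GT, drinking frequency: the
obesity/alcohol axis — against 33 noise features, with marginals shaped
like typical adult checkup panels (lognormal for the skewed labs, ordinal
codes for lifestyle items).

The class effect has magnitude δ (default 0.5) and two δ-proportional
components: the polyp class is **shifted** by δ pooled SDs (log scale for
lognormal features, a per-level log-odds tilt for ordinals) and
**concentrated** — its scale divided by (1 + |δ|). The concentration
component is essential, not decorative: under pure location shifts an
affine-invariant classifier (LDA) on raw features is already
Bayes-optimal, so no transform could improve on the mode-none baseline in
expectation, contradicting the density-shape differences visible in real
checkup features that motivate fitting a KDE on the positive class in the
first place. A narrower positive-class band is exactly the structure that
a positive-class density estimate captures and a linear discriminant does
not. At δ = 0 both components vanish, giving an exact no-signal null.

What the generator does **not** emulate: the real marginal distributions
of any hospital's panel (unpublished), correlations between features
(draws are independent given polyp status), age- or sex-varying effect
sizes, repeat-visit structure, and informative missingness (generated
cohorts are complete). Passing tests therefore demonstrate that the
pipeline recovers the kinds of structure it assumes — band-like
positive-class densities, monotone saturating risks, weak FIT — not that
it attains any particular performance on real patients.

A deterministic 1290-row roster (`fixture_roster()`) encodes the reference
study's published cohort flow exactly — 274 repeat / 8 surgery / 5 IBD
exclusions leaving 1003 eligible (611 men), nested polyp-size counts
547/210/113/93, 704 FIT-positive — with synthetic feature values; only the
tallies are faithful, and the screening context (21,447 screened, 1133
FIT-positive) rides along as metadata.

## Problem sizes in the shipped checks

The packaged checks run at sizes chosen to make their statistics
meaningful while staying desk-sized: the transform-vs-raw contrast and the
no-signal null use 10 cohorts of 1000 men each with a
{logistic regression, Gaussian process, LDA} zoo (the contrast) and a
{logistic regression, LDA} zoo with the full transform grid (the null);
planted-feature recovery uses 10 cohorts of 600 records with 2 informative
(δ = 1) + 3 noise features. The null check bounds the **mean** selected
test MCC over the 10 seeds: the final selection step maximizes test MCC
over 6 finalists, so single-seed values fluctuate with sd ≈ 0.065 at test
n = 250, while systematic leakage would shift the mean.

## Known limitations

* The per-feature transform ignores feature interactions; a joint density
  is out of scope by design.
* The sigmoid variant discards genuine non-monotone risk (e.g. U-shaped
  associations) on the clamped side.
* Decision-function scores are min–max scaled per model, so scores are
  comparable within a model but not across models.
* The elimination path is greedy; it records one candidate per step and
  cannot revisit a dropped feature.
* Ordinal lifestyle codes are treated as numeric throughout, matching the
  reference pipeline's handling; with 2–3 levels their KDEs are crude, and
  the drinking-volume subgroup coding {0,1,2} claims no fidelity to any
  particular questionnaire.
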