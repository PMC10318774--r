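# polypkde

Risk stratification for colorectal neoplasia from routine health-checkup
data. Colonoscopy is the definitive screening test but is too scarce to
offer to everyone; stool-based occult-blood screening (FIT) is cheap but
weakly discriminative and often disregarded. `polypkde` implements a
pipeline that turns the ~39 physical, lifestyle and blood-test measurements
collected at an ordinary checkup into a per-patient *polyp score*, so that
clinicians can prioritise colonoscopy referrals and counsel patients on the
biomarkers driving their risk.

## The method

The core difficulty is that checkup features have heavily overlapping
class-conditional distributions between patients with and without polyps.
The pipeline's central move is a per-feature probabilistic transform built
from the polyp-positive class:

1. For each feature, fit a Gaussian kernel density estimate on the values
   of patients **with** polyps in the training split,
   `f̂_h(x) = (1/nh) Σ_i φ((x − x_i)/h)`, evaluated exactly on a 512-point
   grid spanning the data ± 3h.
2. Rescale to unit maximum and raise to an integer exponent `e ∈ {1..4}`:
   `T(x) = (f̂_h(x) / max f̂_h)^e`. Values near the risk mode map near 1;
   the exponent sharpens the contrast.
3. Optionally clamp one side of the curve to 1 (the *sigmoid-like* variant):
   risk saturates for values beyond the density maximum, in a per-feature
   direction (e.g. higher for waist circumference, lower for HDL). The
   result is a monotone risk-saturation curve per biomarker.

Candidate models — a grid over polyp-size thresholds (0/6/8/10 mm, patients
with only sub-threshold polyps count as negative), transform variants and
exponents, and a ten-classifier zoo — are scored by stratified
cross-validated **Matthews correlation coefficient**

    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

with backward feature elimination down to 3 features; the top 6 candidates
are refit and the test-set MCC argmax wins. Shapley-value attribution ranks
the features behind each score, and the sigmoid curves double as a
counselling report (a transformed value near 1 flags a biomarker sitting in
its risk-saturated range).

The hospital cohort the pipeline was developed on is proprietary, so the
package ships a synthetic-cohort generator (sex-stratified, six informative
features on the obesity/alcohol axis against 33 noise features, banded
polyp-size law, configurable FIT error rates) plus a deterministic 1290-row
roster reproducing the reference study's published cohort-flow tallies.

## Worked example

```r
library(polypkde)
cohort <- generate_cohort(synthetic_spec(seed = 7))   # 1000 men, 1000 women
fit <- fit_pipeline(cohort, sexes = "male", thresholds = 0,
                    modes = c("none", "sigmoid_kde"), exponents = 1:4,
                    classifiers = c("logistic_regression", "lda"), seed = 7)
sel <- fit$sexes$male$selection
sel$best$name
#> [1] "0 S-SKDE-1E-LDA"
sel$metrics
#> n=250  TP=45 TN=151 FP=26 FN=28
#> sens=0.616 spec=0.853 acc=0.784 auc=0.861 mcc=0.473
fit_baseline_metrics(prepare_cohort(cohort)$male, 0)
#> n=1000  TP=86 TN=635 FP=73 FN=206
#> sens=0.295 spec=0.897 acc=0.721 auc=NA mcc=0.238
```

The winning candidate is named `<threshold> S-<transform>-<exponent>E-<classifier>`:
here a sigmoid-KDE transform at exponent 1 feeding linear discriminant
analysis, labelling any recorded polyp (threshold 0 mm) as positive. Its
held-out MCC of 0.47 roughly doubles the FIT baseline's 0.24 on the same
cohort — the qualitative pattern the pipeline is designed to exhibit.

The numbered scripts under `analysis/` run the full study on the default
synthetic cohorts: `01_simulate.R` (cohorts + reference cohort flow),
`02_screen_features.R` (Kruskal–Wallis screen, exported transform curves),
`03_fit_grid.R` (the optimization grid and model selection),
`04_evaluate.R` (metrics, ROC, FIT comparison, score distributions),
`05_attribution.R` (Shapley importance, per-patient report). Each writes
its tables under `results/`.

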