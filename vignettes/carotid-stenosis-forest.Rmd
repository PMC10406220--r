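---
title: "Classifying asymptomatic carotid stenosis from hemodynamic MRI features: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying asymptomatic carotid stenosis from hemodynamic MRI features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Asymptomatic, unilateral, high-grade internal carotid artery stenosis (ICAS)
impairs cerebral hemodynamics most strongly inside *individual watershed
areas* (iWSAs) — subject-specific border zones between vascular territories.
Eight quantitative MRI parameters probe this impairment: cerebrovascular
reactivity (CVR, BOLD β), relative cerebral blood volume (CBV, %), relative
oxygen extraction fraction (OEF), oxygen extraction capacity (OEC),
capillary transit-time heterogeneity (CTH, s), mean transit time (MTT, s),
time to peak (TTP, s) and cerebral blood flow (CBF, ml/100 g/min). Averaging
each parameter over gray- and white-matter volumes of interest inside and
outside the iWSA, per hemisphere, plus interhemispheric differences, yields
12 features per parameter — 96 in total — on which a random-forest
classifier separates patients from age-matched controls, ranks the features
by permutation importance, and relates each patient's misclassification
probability to cognition.

`carotidrf` implements this pipeline end to end, driven by a synthetic
cohort generator calibrated to the published group statistics, so that every
stage is testable without access to the original imaging data. The numbered
scripts under `analysis/` are thin drivers over the package functions.

## The synthetic cohort generator

`simulate_cohort()` draws, per subject, the 64 VOI means (8 parameters × 2
tissues × 2 zones × 2 hemispheres) from a multivariate normal whose marginal
means and SDs equal the group-statistics fixture
(`load_default_parameter_table()`), for 24 patients and 24 controls by
default.

**Correlation structure.** Inter-feature correlations are not part of the
published summary statistics, yet they control the variance of the
interhemispheric difference features and hence classifier behavior. We use
block equicorrelation as the simplest structure with the right anatomy:
`rho_voi = 0.5` between VOIs of the same parameter and `rho_hemi = 0.8`
between hemispheric twins (hemodynamic parameters are strongly bilaterally
correlated; difference features then have realistically small variance).
Both are configuration knobs; the 8×8 per-parameter block is provably
positive definite for the defaults, and a non-positive-definite
configuration fails with a diagnostic rather than silently.

**Severity.** The cognition subanalysis requires a patient subpopulation the
classifier reliably catches and a minority it does not. Severity is a binary
latent: a fraction `severity_fraction = 17/22` of patients is *severe*, the
rest *mild*. Severe patients are shifted by `severity_feature_shift` (default
0.5) times the patient-vs-control mean difference of every feature, away
from controls; mild patients receive the opposite, size-weighted shift so
the patient-group marginal means stay exactly calibrated. At the defaults
mild patients therefore sit at the control centroid — the synthetic analog
of the handful of patients that published work found misclassified in most
repetitions. Any nonzero contrast necessarily inflates the patient-group
marginal SDs above the fixture SDs (for CVR no noise reduction could
compensate), so SD calibration is exact only at
`severity_feature_shift = 0`; mean calibration is exact always.

**Clinical covariates.** Cognitive scores (TMT-A/B, MMSE) and NASCET grade
of patients are drawn from the severe/mild subgroup fixtures; their
17:5 mixture reproduces the published patient-group marginal (e.g. TMT-B
(17·152.5 + 5·94.4)/22 = 139.3 s). Bounded scores (MMSE ≤ 30, times > 0,
NASCET in [70, 99], STAI in [20, 80]) are drawn from truncated normals whose
location is moment-matched by root finding so that the *sample mean* equals
the fixture mean — plain truncation would bias NASCET upward and MMSE
downward by more than the calibration tolerance. The realized SD of a
strongly truncated score (notably BDI) is somewhat below its nominal value;
this is the price of exact mean calibration. Medication indicators are
independent Bernoulli draws at the published prevalences; a medication
count column sums them. Controls get a pseudo-ipsilateral side drawn
uniformly so their feature space carries no systematic lateralization. Two
patients (configurable) lack cognitive testing and are excluded from the
cognition subanalysis.

**Missingness.** Real parameter maps are excluded map-wise for quality, so
`inject_missingness()` removes, per parameter, all 8 VOI slots for a drawn
subset of subjects — never a subset of a subject's VOIs. The default counts
(CVR 14; TTP, MTT, OEC, CBV, CTH 7; CBF, OEF 5 of 48 subjects) give 59/384
excluded subject-by-parameter entries, about 15%.

**Zone-effect concentration.** `iwsa_effect_scale > 1` multiplies the
inside-iWSA group difference and subtracts the added amount from the
outside-zone difference, so the whole-tissue (zone-averaged) difference is
unchanged. This isolates exactly the quantity of interest — *is the group
contrast concentrated in the watershed?* — without touching overall
difficulty; at the default 1.0 the fixture calibration is untouched. Note
that at 1.0 the zone-resolved table has no information advantage over
whole-tissue averaging (which denoises); an ordering between VOI definitions
is only expected, and only tested, for scales above 1.

**What the generator does not emulate.** Real inter-feature correlations
(unknown), non-Gaussian marginals, spatial autocorrelation of maps,
scanner/vendor effects, and the manual editing steps of watershed
delineation. Passing tests therefore demonstrate correctness of the
*pipeline* under controlled conditions, not reproduction of the published
classifier metrics, which depend on the unpublished correlation structure of
the real 48-subject sample.

## Map mode

`simulate_volumes()` builds a small ellipsoidal phantom (32×32×16 voxels by
default): white-matter core, gray-matter shell, and a watershed band at the
GM/WM interface holding exactly 10% of brain voxels, with TTP elevated
inside the band (default +2 s) and all parameter maps set to their
(tissue, zone, hemisphere, group) fixture values plus optional noise. T2 and
T2* maps are emitted by inverting the mq-BOLD model, so
`compute_r2prime()` (R2′ = 1/T2* − 1/T2) followed by `compute_roef()`
(rOEF = R2′/(c·rCBV), c = 317 Hz at 3 T) recovers the OEF map; rCBV must be
a fraction, and percent-scaled input is detected and refused.

Watershed segmentation follows the percentile rule: voxels whose (optionally
Gaussian-smoothed) TTP strictly exceeds the 90th percentile of the in-brain
distribution. The smoothing kernel width is unspecified in the source
procedure; the default is FWHM 4 (voxel units), configurable, and 0 disables
smoothing — on the coarse phantom, where the watershed band is one to two
voxels thick, smoothing blurs the band and only unsmoothed segmentation
recovers it exactly. Tissue masks threshold probability maps strictly at
p > 0.70; voxels passing both thresholds go to the tissue with the higher
probability, ties to gray matter. Manual editing of cortical watershed zones
and vessel/ventricle exclusion are out of scope.

The interhemispheric difference is defined as ipsi − contra (signed); the
source wording does not fix the sign, so this is a documented convention,
and the hemisphere-swap test verifies the resulting antisymmetry.

## The forest

`fit_forest()` grows bagged CART classification trees (default 300) on
bootstrap samples drawn with replacement (in-bag/out-of-bag membership
recorded per tree). At each node `mtry = floor(sqrt(p))` features are drawn;
the split maximizes Gini impurity decrease over rows where the candidate is
observed, scaled by the observed fraction. Trees grow to purity (minimum 2
rows to split) — the classification defaults of the reference
implementations. Up to 5 surrogate splits per node, ranked by agreement with
the primary split and required to beat the majority-direction baseline,
route rows with missing primary values; the majority child is the last
resort. Prediction is the majority vote over trees; exact vote ties go to
the control class — the conservative choice for a screening framing.
Forests serialize to a documented JSON structure (`write_forest_json()`)
and deserialize to a predicting ensemble.

Permutation importance permutes one feature across a tree's out-of-bag rows
(one fresh permutation per tree — the behavior of the reference
implementation; a shared permutation per forest would be the alternative),
and reports mean error increase over trees divided by its SD across trees
(0 if the SD is 0, e.g. for never-used features). Two null facts matter for
interpretation: (i) on an all-noise problem the score mean is slightly
*negative*, because the OOB set is the sampling complement of the in-bag
data each tree overfits, so permutation moves OOB error toward chance from
above — a property shared by the reference implementation and asserted in a
dedicated test; (ii) noise features alongside a dominant predictor score
zero on average, because trees bypass them. The recursive-elimination floor
of 0.1 should be read against this near-zero, slightly negative null.

## Feature selection and evaluation

`recursive_feature_elimination()` repeatedly drops the lowest-ranked
`max(1, floor(0.10·m))` features (floor guarantees progress) until all
survivors score above 0.1. `per_parameter_dedup()` then keeps, per
parameter, the best hemispheric feature and the best difference feature —
reading the "highest ranked VOI and/or VOI difference" rule as both-if-
present. `random_subset_validation()` checks rank stability on random
12-feature subsets; because subset and full rankings are computed on the
same data set, even noise features show some rank consistency, so the
report is a consistency measure, not a significance test.

Cross-validation uses stratified folds (per-class counts differing by at
most one, remainders rotated so overall sizes also differ by at most one);
plain random assignment is available but risks single-class training splits
at n = 48, which the package refuses to fit. Nested selection recomputes
importances per outer fold on the training rows only (reduced repetitions,
configurable), deduplicates, truncates to 12 candidates (dedup can yield up
to 16; 12 nested model sizes are trained), and evaluates each size on the
held-out fold; the selection function receives the training partition only,
which a poisoning test verifies. ROC curves use the vote fraction with
"positive if score ≥ threshold"; AUC is trapezoidal and equals the
Mann–Whitney concordance; the Youden point breaks ties toward the lowest
threshold (maximal sensitivity). DeLong's test uses the fast midrank
formulation, validated against a naive O(n²) oracle; in
`compare_voi_definitions()` it is applied to per-subject out-of-fold scores
averaged over fold-assignment repetitions. Repeated accuracies are
summarized by mean ± SD without significance testing, since overlapping
training sets leave no unbiased variance estimator.

## Misclassification and cognition

`misclassification_probability()` refits the full-cohort forest repeatedly
(default 1,000) and tallies, per subject, incorrect *out-of-bag*
predictions. Resubstitution predictions would be near-perfect for a purity-
grown forest and carry no signal, so OOB is the only reading that produces
the observed misclassification behavior. Patients above the 50% threshold
form the frequently-misclassified subgroup (exactly 50% counts as correctly
classified; the boundary is unspecified in the source); controls are
excluded. `compare_subgroups()` applies a two-tailed t-test when both
subgroups pass a Shapiro–Wilk screen at α = 0.05, otherwise the
Mann–Whitney U test, and always reports the Mann–Whitney p alongside.
A power caveat: at the fixture effect sizes (TMT-B 152.5 ± 66.9 vs
94.4 ± 26.1) with subgroups of ~15–17 and 5, the exact Mann–Whitney test
has power near one half, so single-cohort significance is a coin flip even
with perfect subgrouping — the direction of the difference is the robust
quantity.

## Problem sizes and determinism

All randomness flows through explicit seeds; every repetition derives its
own seed from a master seed, and identical configurations give bit-identical
results (including byte-identical JSON summaries from `run_pipeline()`).
The package defaults mirror the reference procedure (300 trees,
1,000-repetition importance averaging, 100-repetition evaluation,
1,000-repetition misclassification profiling). The analysis scripts and the
test suite run reduced sizes chosen to keep a desk-scale run comfortable
while leaving every estimate's Monte-Carlo error well inside the tested
tolerances: 50–100 trees, 5–50 importance repetitions, 10 evaluation
repetitions, 100–300 misclassification repetitions, and 20-seed property
checks. Calibration checks use 10,000 subjects per group, where three
standard errors of a mean are a fraction of a percent of its value.

## Known limitations

* Published classifier metrics are not reproduction targets: they depend on
  the unpublished inter-feature correlations of the real sample.
* The phantom is geometric; it validates mask logic and averaging, not
  registration or segmentation of real anatomy.
* Binary severity is the simplest latent consistent with a two-subgroup
  report; real severity is graded.
* Bounded clinical scores trade exact SD reproduction for exact mean
  reproduction under truncation.
* Only binary classification, unweighted classes, and the eight fixed
  parameters are supported.
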