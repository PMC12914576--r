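---
title: "Probabilistic lesion mapping of glioma: models, parameters and design"
author: "gliomamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic lesion mapping of glioma: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomamap)
```

# The problem

A cohort of patients with glioma, each contributing a binary tumour
segmentation registered to one common voxel grid, supports three families of
questions:

1. *Where* do gliomas occur — overall and within subgroups defined by tumour
   volume, molecular subtype (IDH, MGMT, 1p/19q), age, sex or survival?
2. *Which voxels'* lesion status is statistically associated with a
   subject-level attribute?
3. Does *location* carry prognostic information beyond age and tumour size?

`gliomamap` implements the corresponding pipeline: frequency (sum) maps,
mass-univariate per-voxel regression with FDR control, atlas ROI summaries,
and an overlap-score survival classifier with paired ROC comparison.

# Models and assumptions

## Frequency maps and tertiles

A frequency map counts, per voxel, the subjects whose lesion covers it;
percentages divide by the subset size. No smoothing is applied — the map is
the raw sum of binary masks, so `sum(counts)` always equals the summed
lesion volumes (in voxels) of the contributing subjects, a conservation law
the tests assert exactly.

Volume tertiles use the linear-interpolation empirical quantile (R's default
type 7) at 1/3 and 2/3. A volume exactly equal to a cutoff is labelled
`medium`: the convention matches printed ranges of the form "< q1",
"q1–q2", "> q2". With distinct volumes the three groups differ in size by at
most two subjects; ties at a cutoff can enlarge `medium`, which is why the
boundary convention is stated rather than silent.

## Per-voxel models

All per-voxel models treat the **attribute as the response and the binary
lesion indicator as the predictor**, one attribute at a time, with no
covariates and no interactions. This is the only direction in which a
regression on a single binary predictor with `n` subjects has `n − 2`
degrees of freedom, which is how the t-maps are reported.

* Continuous attributes (`volume_ml`, `age_years`, `os_days`):
  `y_i = β0 + β1 m_iv` by least squares. The t of `β1` is algebraically the
  pooled-variance two-sample t comparing lesioned and non-lesioned
  subjects, and is computed in that vectorized form; the test suite verifies
  equality with per-voxel `t.test(var.equal = TRUE)` to below 1e-8.
* Binary subgroups (`idh`, `mgmt`, `codel_1p19q`, `sex`):
  `logit P(class = 1 | m_v) = β0 + β1 m_v` by maximum likelihood. Because
  the model is saturated in a 2×2 table, Newton iterations on the per-voxel
  sufficient statistics (class × lesion cell counts) converge in a few
  steps; the implementation iterates to a score norm below 1e-8 (max 25
  iterations) simultaneously across voxels. The Wald z of `β1` is reported
  with its closed-form standard error `sqrt(1/a + 1/b + 1/c + 1/d)`.
  Voxels with an empty cell (complete or quasi-complete separation) are
  marked invalid and counted rather than Firth-corrected: this preserves the
  Wald interpretation and makes the exclusion auditable.

**Coverage.** A voxel is analysable only if at least `min_count` subjects
are lesioned there *and* at least `min_count` are not (default 5,
configurable, recorded in the output metadata). Voxels lesioned in almost
none or almost all subjects carry no usable contrast and would otherwise
produce unstable fits.

**Inference.** Tests are two-sided throughout; t-maps are signed with
symmetric thresholds. FDR is Benjamini–Hochberg, computed across the valid
voxels of one map at a time (one contrast, one family), never across maps.
Both raw-p and FDR thresholding are available because reporting conventions
differ on whether "P < 0.001" refers to raw or adjusted values; the
`thresholded_map` records which was used. Survival can be analysed either as
a continuous t-map (`os_days`) or as banded frequency maps (< 6, 6–12,
12–18, > 18 months); both modes exist because banded displays and continuous
tests answer slightly different questions.

## ROI analysis

ROI lesion load is `|mask ∩ ROI| / |ROI|` — the fraction of the region
lesioned. This is size-invariant per region; the alternative normalization
by tumour volume (`normalize = "tumour"`) is available behind a flag. The
per-ROI subgroup test is a univariate logistic regression of the class on
the load with BH correction across the atlas's testable ROIs; constant-load
and separated ROIs are flagged untestable and excluded from the BH family.
This test is documented as the package's interpretation of "ROI association
analysis" — it is one defensible choice among several (rank tests, load
comparisons), stated rather than assumed. A synthetic octant atlas (8 equal
blocks) ships for tests and examples; anatomical atlases are read from any
integer-labelled NIfTI plus a `label,name` CSV.

## Survival classification

The *overlap score* of a subject is the **mean** of the overall-survival
t-map over the subject's lesion voxels restricted to the map's valid
voxels. The mean (not the sum) is used so that the location feature is not
trivially confounded with tumour volume — volume enters the comparison as
its own model; the sum variant is available behind a flag. Survival is
dichotomized at 365 days, strictly greater meaning `long`; the cutoff is
configurable and the default matches a cohort whose median survival sits at
about one year.

Three nested logistic models — `age+overlap`, `age+volume`, `age` — are
fitted by maximum likelihood and compared by ROC. AUC uses midrank tie
handling (equal to the Mann–Whitney statistic with ties counted 1/2, and to
the trapezoidal area of the returned curve). Paired AUC comparison is
DeLong's test via midrank structural components in O(n log n); the tests
cross-check both AUC and the DeLong z/p against `pROC` and a 10,000-rep
paired bootstrap of the AUC-difference variance.

**Evaluation modes.** `in_sample` (default) fits the survival map and the
classifiers on all complete cases and evaluates on the same subjects. The
overlap feature is then trained on the subjects it is scored on — a
circular, optimistic estimate; it is provided because it mirrors common
practice and the published display convention. `loo` is an exact
leave-one-out: for each held-out subject the survival map is refit without
that subject (sufficient-statistic downdating, O(V)), **every** subject's
overlap feature is recomputed against that held-out map (two matrix–vector
products), and the classifier is refit on the remaining n − 1 subjects.
This costs O(n²V) overall but is BLAS-bound and runs in seconds to tens of
seconds at the problem sizes below. An earlier design that reused one
jackknifed feature per subject across folds was rejected: it gives the
overlap model a learnable self-exclusion structure that raw features lack,
biasing null comparisons between models.

# The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth. Per
subject it draws a group label, a lesion centre from an isotropic Gaussian
at the group's mean, an equivalent radius from a lognormal, and rasterizes
an axis-aligned ellipsoid (per-axis ratios Uniform(0.7, 1.3)) clipped to the
grid; `volume_ml` is always the realized mask volume. Survival follows a
log-linear accelerated-time model,

    os = baseline × exp(−β_loc · overlap − β_age · (age − mean)/10) × exp(N(0, 0.3)),

where `overlap` is the mean of a smooth latent risk field (Gaussian bump,
peak 1, SD 5 voxels at the first group's mean centre) over the lesion. The
log-linear form (rather than a proportional-hazards model) keeps the ground
truth closed-form for parameter-recovery tests. One master seed drives
deterministic per-subject substreams (counter-offset hashing), so cohorts
are bit-reproducible and independent of generation order, and the caller's
RNG state is left untouched.

Default parameters, with reasons:

| parameter | default | why |
|---|---|---|
| grid, voxel | 32³, 2 mm | toy analogue of a downsampled standard space; 262 ml "brain" |
| radius lognormal | meanlog log(6), sdlog 0.35 (voxels) | median lesion ≈ 7 ml ≈ 2.8% of the grid volume, the relative size of a ~40 ml tumour in a ~1400 ml brain; sdlog reproduces a volume spread whose tertile cutoffs sit at roughly 0.6× and 1.6× the median |
| group fractions | 80% / 20% | wild-type : mutant ratio of pooled clinical cohorts |
| centre SD | 5 voxels | lesion placement must vary on the scale of the risk field so that survival is genuinely *location*-driven: at smaller spreads the mean-overlap of a lesion is largely a function of its volume (big lesions dilute away from the peak) and the location feature collapses onto volume |
| age | Normal(58.8, 14.3), truncated 18–90 | adult glioma demographics |
| β_loc, β_age | 1.5 per unit overlap, 0.3 per decade | overlap spans ≈ 0.1–0.8 across subjects, so location shifts survival by up to ~3×; age contributes a visible but weaker signal, keeping the expected model ordering age+overlap > age+volume ≈ age |
| baseline | 700 days | places the cohort's median survival at ≈ 365 days, so the 1-year dichotomization cutoff is the group median; the resulting OS mean is in the several-hundred-day range typical of pooled glioma cohorts |
| molecular sub-labels | MGMT methylated 56% of wild-type; co-deleted 33% of mutant; female 39% | pooled cohort proportions |

Null cohorts in tests set `β_loc = β_age = 0` **and** `baseline = 365`, so
the median still sits at the cutoff and the survival classes stay balanced
under the null.

**What the generator does not emulate:** MRI intensities, registration
error, scanner and segmentation heterogeneity across source databases,
infiltrative (non-ellipsoidal) lesion shapes, censoring of survival, and
missing clinical values (tables are complete; missing-value handling is
exercised separately). Passing tests therefore demonstrate the statistical
machinery on idealized geometry, not robustness to real-data artefacts.

# Numerical choices and degenerate inputs

- Masks binarize at `> 0.5`, accepting integer label maps and probabilistic
  segmentations; multi-compartment labels collapse to any-nonzero.
  Empty masks warn and are flagged excludable rather than erroring.
- Grids must agree exactly in shape and within 1e-4 in voxel size and
  affine; voxel indexing is 0-based, world coordinates only via the affine.
- Missing clinical values are explicit `NA` (empty CSV cells), never 0;
  every analysis subsets to complete cases of its own attribute and reports
  `n_used`.
- A constant attribute yields t = 0 (not NaN) at every valid voxel; a zero
  pooled variance with a nonzero mean difference marks the voxel invalid.
- `critical_t(alpha, df)` is the exact two-sided t quantile; at df = 2162 it
  gives 3.2950 for α = 0.001 (the conventionally printed 3.29 is the normal
  quantile) and 1.9611 for α = 0.05.
- DeLong with zero difference-variance: equal AUCs give z = 0, p = 1
  (self-comparison); differing AUCs with zero variance raise an error.
- Lesions that miss the survival map's valid region produce a missing
  overlap score and are dropped from the affected model with a warning.

# Problem sizes used by the tests and the acceptance script

Simulation-based checks run at deliberately chosen sizes: oracle-equivalence
at n = 60 on a 16³ grid; permutation null calibration at n = 400 on 32³
(≥ 2000 valid voxels, 20 permutations averaged); leave-one-out null AUC at
n = 500 on 16³, averaged over 5 replicate cohorts; planted-effect recovery
at n = 400 with a 10-voxel two-group offset in a compact (centre SD 3)
geometry; the full-cohort bookkeeping at n = 2164 single-voxel lesions on a
4³ grid. The planted-effect ground truth is the region where the
generator's true lesion-probability fields (estimated from an independent
n = 2000 simulation) differ by at least 0.15 — the minimal difference a
two-proportion comparison at 200 subjects per group detects with ~80% power
at the FDR-adjusted level — and recovery is summarized by the Dice overlap
of the FDR rejection set with that region.

# Known limitations

- The in-sample overlap feature is circular by construction; only the `loo`
  mode gives honest prediction estimates, and even loo linear-predictor
  scores of near-chance classifiers are known to be mildly pessimistic
  (held-out scores anti-correlate with the held-out label through
  self-exclusion).
- DeLong's test assumes fixed scores. Applied to leave-one-out (refit)
  scores its p-values are anticonservative because refitting variability is
  not in the variance; DeLong comparisons should be read at face value only
  for the in-sample mode, and cross-validated comparisons treated as
  descriptive.
- Per-voxel tests are spatially dependent (subjects span many voxels); FDR
  controls the expected false-discovery fraction per map but the realized
  voxel-level error rate of any single map varies widely, which is why
  calibration is assessed as an average over permutations.
- The ROI association test is the package's documented interpretation, not
  a reproduction of any particular published ROI analysis.
- No censoring model: survival modelling requires observed survival days
  and excludes subjects without them.
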