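# gliomamap

Probabilistic lesion mapping of glioma location, molecular subtype and
survival, for cohorts of co-registered binary tumour segmentations.

## What it is for

Gliomas are not uniformly distributed in the brain: tumour size, molecular
subtype (IDH status, MGMT promoter methylation, 1p/19q co-deletion), age and
overall survival all pattern with lesion location. Given a cohort of binary
tumour masks on one common voxel grid (e.g. MNI space) plus a clinical table,
`gliomamap` provides the standard voxel-based lesion-mapping toolchain:

- **Frequency (sum) maps** — per-voxel counts/percentages of subjects whose
  lesion covers each voxel, overall and for subgroups (volume tertiles,
  molecular subtypes, age decades, survival bands).
- **Mass-univariate voxel statistics** — at every analysable voxel `v`, an
  independent model of the subject attribute on the binary lesion indicator
  `m_v`:
  - continuous attributes: `y_i = β0 + β1 m_iv`, reported as the t statistic
    of `β1` with `df = n − 2` (algebraically the pooled-variance two-sample
    t between lesioned and non-lesioned subjects at `v`);
  - binary subgroups: `logit P(class | m_v) = β0 + β1 m_v` by maximum
    likelihood, reported as the Wald z of `β1`, with separation flagged;
  - Benjamini–Hochberg FDR across the map's valid voxels, plus uncorrected
    and FDR thresholding at any α.
- **ROI analysis** — per-subject lesion load (fraction of each atlas ROI
  lesioned), with univariate logistic association tests per ROI and BH
  correction across the atlas.
- **Survival classification** — each tumour's *overlap score* (mean of the
  voxel-wise overall-survival t-map over the lesion), nested logistic models
  (`age+overlap`, `age+volume`, `age`) for survival > 1 year, ROC/AUC with
  midrank tie handling, and paired AUC comparison by DeLong's test. Both
  in-sample and exact leave-one-out evaluation (map and classifier refit
  per held-out subject) are provided.
- **Synthetic cohorts** — a generator planting ellipsoid lesions with
  group-dependent spatial placement, lognormal volumes, and survival driven
  by lesion location plus age, so the entire pipeline is testable without
  access-restricted imaging data.

Masks, atlases and all output maps are NIfTI-1 (via `RNifti`); clinical
tables are CSV with the header
`subject_id,age_years,sex,os_days,volume_ml,idh,mgmt,codel_1p19q`.

## Worked example

```r
library(gliomamap)

sim    <- generate_cohort(synth_params(n_subjects = 200, seed = 42))
cohort <- sim$cohort
cohort
#> <glioma_cohort> n = 200 subjects
#>   grid 32x32x32, voxels 2x2x2 mm
#>   volume_ml: median 8.2 [0.3, 87.6]
#>   idh: wildtype=154, mutant=46 (missing 0)
#>   ...

sum_map(cohort)
#> <frequency_map> subset 'all', n = 200
#>   peak overlap: 78 subjects (39.0%) at voxel [16, 16, 13]

tmap <- voxelwise_linear(cohort, "age_years")
tmap
#> <stat_map> t-map of 'age_years', n_used = 200, df = 198
#>   valid voxels: 15144 | separated/non-converged: 0
#>   stat range: [-2.57, 2.99]; min q = 1

zmap <- voxelwise_logistic(cohort, "idh")
zmap
#> <stat_map> z-map of 'idh', n_used = 200
#>   valid voxels: 13675 | separated/non-converged: 1469
#>   stat range: [-2.60, 3.91]; min q = 0.113

survival_roc(cohort, eval = "in_sample")
#> <survival_report> eval = in_sample , n_used = 200 , cutoff = 365 days
#>   AUC age+overlap  = 0.897
#>   AUC age+volume   = 0.853
#>   AUC age          = 0.831
#>   DeLong age+overlap vs age+volume: Z = 1.87, p = 0.0608
#>   DeLong age+overlap vs age: Z = 2.93, p = 0.00342
#>   DeLong age+volume vs age: Z = 1.60, p = 0.111
```

Reading: the frequency map peaks where lesions concentrate (here 39% of
subjects overlap the modal voxel); the t/z maps localize attribute–location
associations with their FDR-adjusted q-values; and the survival report shows
that adding the location-derived overlap score to age improves
classification of 1-year survival while tumour volume adds little — the
location signal planted by the generator.

The whole pipeline (simulate/load → maps → voxel stats → ROI table →
survival report, with config snapshot and stage log) runs via
`run_pipeline(run_config(...))`, or from a shell through the thin wrapper
`inst/cli/gliomamap.R` (subcommands `simulate`, `summap`, `voxelstats`,
`roi`, `survival-roc`, `run`).

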