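Package: gliomamap
Title: Probabilistic Lesion Mapping of Glioma Location, Molecular Subtype
    and Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise probabilistic mapping of glioma location from cohorts
    of co-registered binary tumour segmentations on a common grid. Aggregates
    masks into lesion frequency (sum) maps overall and for clinical or
    molecular subgroups, relates lesion location to per-subject attributes by
    mass-univariate per-voxel linear and logistic regression with
    Benjamini-Hochberg false discovery rate control, summarizes lesion burden
    within atlas regions of interest, and evaluates survival classifiers whose
    key feature is each tumour's overlap with a voxel-wise survival map, with
    paired ROC comparison by DeLong's test. Includes a synthetic-cohort
    generator with planted spatial structure so the whole pipeline is testable
    without access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
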