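# Fixture builders: tiny cohorts constructed in code.

# A mask with lesion at the given 1-based voxel indices (matrix n x 3 or
# vector of linear indices).
make_mask <- function(id, shape = c(4, 4, 4), voxels = NULL,
                      voxel_size = c(1, 1, 1)) {
  arr <- array(0, dim = shape)
  if (!is.null(voxels)) {
    if (is.matrix(voxels)) arr[voxels] <- 1 else arr[voxels] <- 1
  }
  suppressWarnings(mask_volume(arr, id, voxel_size = voxel_size))
}

# Clinical row skeleton with sensible defaults.
make_clinical <- function(ids, age = 60, sex = "female", os = 400,
                          volume = NA, idh = "wildtype", mgmt = NA,
                          codel = NA) {
  n <- length(ids)
  clinical_table(data.frame(
    subject_id = ids,
    age_years = rep_len(age, n), sex = rep_len(sex, n),
    os_days = rep_len(os, n), volume_ml = rep_len(volume, n),
    idh = rep_len(idh, n), mgmt = rep_len(mgmt, n),
    codel_1p19q = rep_len(codel, n),
    stringsAsFactors = FALSE))
}

# Random small cohort: n subjects with random blob-free masks (each voxel
# lesioned independently), guaranteed non-empty; clinical values random.
random_cohort <- function(n, shape = c(6, 6, 6), p_lesion = 0.3, seed = 1,
                          voxel_size = c(1, 1, 1)) {
  set.seed(seed)
  masks <- lapply(seq_len(n), function(i) {
    repeat {
      arr <- array(rbinom(prod(shape), 1, p_lesion), dim = shape)
      if (sum(arr) > 0) break
    }
    mask_volume(arr, sprintf("s%03d", i), voxel_size = voxel_size)
  })
  clin <- clinical_table(data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    age_years = round(runif(n, 20, 85), 1),
    sex = sample(c("female", "male"), n, replace = TRUE),
    os_days = round(rlnorm(n, log(400), 0.6)),
    volume_ml = NA_real_,
    idh = sample(c("wildtype", "mutant"), n, replace = TRUE),
    mgmt = NA, codel_1p19q = NA, stringsAsFactors = FALSE))
  suppressWarnings(suppressMessages(assemble_cohort(masks, clin)))
}
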