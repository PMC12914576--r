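## Synthetic glioma cohorts with planted spatial structure.
##
## Lesions are axis-aligned ellipsoids whose centres depend on a group label
## (the stand-in for molecular subtype), radii are lognormal, and survival
## follows a log-linear accelerated-time model driven by lesion overlap with
## a latent spatial risk field plus age. Downstream statistics only ever see
## binary voxels, so simple geometry suffices to exercise every stage.

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the pooled multi-database glioma cohort the pipeline is
#' designed for, scaled to a 32^3 toy grid with 2 mm voxels: a large
#' IDH-wild-type majority with a spatially shifted IDH-mutant minority,
#' lognormal tumour volumes spanning a realistic relative range, age
#' ~ Normal(58.8, 14.3) truncated to [18, 90] years, and overall survival of
#' a few hundred days modulated by lesion location and age.
#'
#' @param grid_shape integer 3-vector of grid dimensions (voxels).
#' @param voxel_size_mm numeric 3-vector, voxel edge lengths (mm).
#' @param n_subjects number of subjects (>= 2).
#' @param group_fracs named fractions per group, summing to 1. Group names
#'   `idh_wildtype`/`idh_mutant` map onto the IDH factor of the clinical
#'   table; other names are carried through as-is.
#' @param centre_means named list (one 3-vector per group) of mean lesion
#'   centres in 0-based voxel coordinates.
#' @param centre_sd isotropic SD of lesion centres (voxels).
#' @param radius_lognorm `c(meanlog, sdlog)` of the lesion equivalent radius
#'   in voxels; each semi-axis is the radius times an independent
#'   Uniform(0.7, 1.3) axis ratio.
#' @param age_mean_sd `c(mean, sd)` of age in years (truncated to [18, 90]).
#' @param survival_beta_location acceleration per unit risk-field overlap
#'   (overlap = mean risk-field value over the lesion; risk field peaks at 1).
#' @param survival_beta_age acceleration per decade of age above the mean.
#' @param survival_baseline_days baseline survival scale (days).
#' @param seed integer master seed; every subject derives a private
#'   substream from it by counter offset, so generation is reproducible and
#'   independent of subject order.
#' @return object of class `synth_params`.
#' @export
synth_params <- function(grid_shape = c(32, 32, 32),
                         voxel_size_mm = c(2, 2, 2),
                         n_subjects = 2164,
                         group_fracs = c(idh_wildtype = 0.8, idh_mutant = 0.2),
                         centre_means = list(idh_wildtype = c(15, 16, 16),
                                             idh_mutant = c(19, 16, 16)),
                         centre_sd = 5,
                         radius_lognorm = c(meanlog = log(6), sdlog = 0.35),
                         age_mean_sd = c(58.83, 14.3),
                         survival_beta_location = 1.5,
                         survival_beta_age = 0.3,
                         survival_baseline_days = 700,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            n_subjects >= 2, centre_sd >= 0,
            length(radius_lognorm) == 2L, radius_lognorm[2] >= 0,
            length(age_mean_sd) == 2L, age_mean_sd[2] > 0,
            survival_baseline_days > 0)
  if (is.null(names(group_fracs)) || any(!nzchar(names(group_fracs))))
    stop("group_fracs must be named")
  if (abs(sum(group_fracs) - 1) > 1e-8) stop("group fractions must sum to 1")
  if (!all(names(group_fracs) %in% names(centre_means)))
    stop("centre_means must name every group in group_fracs")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 n_subjects = as.integer(n_subjects),
                 group_fracs = group_fracs,
                 centre_means = lapply(centre_means[names(group_fracs)], as.numeric),
                 centre_sd = centre_sd,
                 radius_lognorm = as.numeric(radius_lognorm),
                 age_mean_sd = as.numeric(age_mean_sd),
                 survival_beta_location = survival_beta_location,
                 survival_beta_age = survival_beta_age,
                 survival_baseline_days = survival_baseline_days,
                 seed = as.integer(seed)),
            class = "synth_params")
}

## Deterministic per-subject substream: a counter-offset hash of the master
## seed, kept inside 32-bit integer range.
subject_seed <- function(seed, i, salt = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 9973 + salt * 7919) %%
               2147483647)
}

## Evaluate RNG-consuming code with a private seed, leaving the caller's RNG
## state untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

## Rasterize an axis-aligned ellipsoid on the grid (0-based voxel centres),
## clipped at the edges.
rasterize_ellipsoid <- function(shape, centre, semi_axes) {
  lo <- pmax(0L, floor(centre - semi_axes))
  hi <- pmin(shape - 1L, ceiling(centre + semi_axes))
  arr <- array(0L, dim = shape)
  if (any(lo > hi)) return(arr)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - centre[1]) / semi_axes[1])^2
  dy2 <- ((ys - centre[2]) / semi_axes[2])^2
  dz2 <- ((zs - centre[3]) / semi_axes[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  arr[xs + 1L, ys + 1L, zs + 1L] <- as.integer(inside)
  arr
}

## Smooth nonnegative risk field: Gaussian bump, max 1, centred on `centre`.
make_risk_field <- function(shape, centre, sd = 5) {
  xs <- (0:(shape[1] - 1) - centre[1])^2
  ys <- (0:(shape[2] - 1) - centre[2])^2
  zs <- (0:(shape[3] - 1) - centre[3])^2
  exp(-outer(outer(xs, ys, `+`), zs, `+`) / (2 * sd^2))
}

## Ancestral proportions in the pooled cohort, used to attach molecular
## labels beyond the group factor: MGMT methylation among wild-type and
## 1p19q co-deletion among mutant tumours, plus the female fraction.
synth_label_fracs <- list(mgmt_methylated = 403 / (403 + 312),
                          codel = 102 / (102 + 205),
                          female = 833 / 2123)

#' Generate a synthetic cohort (plus its latent risk field)
#'
#' For each subject: a group is drawn from `group_fracs`; a lesion centre
#' from an isotropic Gaussian at the group's mean (redrawn up to 100 times
#' if the rasterized lesion would be empty, then an error); an equivalent
#' radius from the lognormal; the axis-aligned ellipsoid is rasterized and
#' clipped to the grid. `volume_ml` is always the realized mask volume. Age
#' is Normal(mean, sd) truncated to [18, 90]. Overall survival follows the
#' accelerated-time model
#' `os = baseline * exp(-b_loc * overlap - b_age * (age - mean)/10) * exp(N(0, 0.3))`
#' where `overlap` is the mean risk-field value over the lesion. Molecular
#' labels come from the group (groups named `idh_*`) with MGMT and 1p19q
#' sub-labels assigned at the pooled cohort's observed proportions.
#'
#' @param params a [synth_params()].
#' @return list with `cohort` (a `glioma_cohort`), `risk_field` (3-D array,
#'   max 1), `groups` (named character vector subject -> group), and
#'   `overlap` (named numeric, each subject's risk-field overlap).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  shape <- p$grid_shape
  risk_centre <- p$centre_means[[1]]
  risk <- make_risk_field(shape, risk_centre, sd = 5)
  groups <- names(p$group_fracs)
  cum <- cumsum(p$group_fracs)
  n <- p$n_subjects
  ids <- sprintf("synth%04d", seq_len(n))

  masks <- vector("list", n)
  grp <- character(n)
  age <- numeric(n); osd <- numeric(n); ovl <- numeric(n)
  sex <- character(n); idh <- rep(NA_character_, n)
  mgmt <- rep(NA_character_, n); codel <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    with_seed(subject_seed(p$seed, i), {
      g <- groups[findInterval(stats::runif(1), cum) + 1L]
      grp[i] <- g
      mu <- p$centre_means[[g]]
      mask <- NULL
      for (try in seq_len(100L)) {
        centre <- stats::rnorm(3, mu, p$centre_sd)
        radius <- stats::rlnorm(1, p$radius_lognorm[1], p$radius_lognorm[2])
        axes <- radius * stats::runif(3, 0.7, 1.3)
        cand <- rasterize_ellipsoid(shape, centre, axes)
        if (sum(cand) > 0L) { mask <- cand; break }
      }
      if (is.null(mask))
        stop("subject ", ids[i], ": lesion fell outside the grid in 100 ",
             "consecutive centre draws; check centre_means/centre_sd")
      masks[[i]] <- mask_volume(mask, ids[i], voxel_size = p$voxel_size_mm)

      repeat {
        a <- stats::rnorm(1, p$age_mean_sd[1], p$age_mean_sd[2])
        if (a >= 18 && a <= 90) break
      }
      age[i] <- a
      ovl[i] <- sum(risk * mask) / sum(mask)
      osd[i] <- p$survival_baseline_days *
        exp(-p$survival_beta_location * ovl[i] -
              p$survival_beta_age * (a - p$age_mean_sd[1]) / 10) *
        exp(stats::rnorm(1, 0, 0.3))
      sex[i] <- if (stats::runif(1) < synth_label_fracs$female) "female" else "male"
      if (g == "idh_wildtype") {
        idh[i] <- "wildtype"
        mgmt[i] <- if (stats::runif(1) < synth_label_fracs$mgmt_methylated)
          "methylated" else "unmethylated"
      } else if (g == "idh_mutant") {
        idh[i] <- "mutant"
        codel[i] <- if (stats::runif(1) < synth_label_fracs$codel)
          "codeleted" else "non_codeleted"
      }
    })
  }

  clin <- clinical_table(data.frame(
    subject_id = ids, age_years = age, sex = sex, os_days = osd,
    volume_ml = vapply(masks, compute_volume_ml, numeric(1)),
    idh = idh, mgmt = mgmt, codel_1p19q = codel,
    stringsAsFactors = FALSE))
  cohort <- suppressMessages(assemble_cohort(masks, clin))
  list(cohort = cohort,
       risk_field = risk,
       groups = stats::setNames(grp, ids),
       overlap = stats::setNames(ovl, ids),
       params = p)
}

#' Generate a two-group cohort with a planted spatial offset
#'
#' Group B lesion centres are shifted by `offset` (voxels) relative to group
#' A; everything else is identical. The returned object additionally carries
#' the two group labels, the ground-truth centres, and per-group membership,
#' supporting planted-effect recovery tests.
#'
#' @param params a [synth_params()] with exactly two groups.
#' @param offset numeric 3-vector displacement of group B (voxels).
#' @return as [generate_cohort()].
#' @export
plant_two_group_effect <- function(params, offset) {
  stopifnot(inherits(params, "synth_params"), length(offset) == 3L)
  if (length(params$group_fracs) != 2L)
    stop("plant_two_group_effect requires exactly two groups")
  base <- params$centre_means[[1]]
  params$centre_means[[2]] <- base + as.numeric(offset)
  generate_cohort(params)
}

#' Write a synthetic cohort to disk as an on-disk fixture
#'
#' Emits one NIfTI mask per subject (`masks/<id>.nii.gz`), `clinical.csv`,
#' the risk field (`risk_field.nii.gz`) and a `params.yaml` snapshot.
#'
#' @param sim result of [generate_cohort()] or [plant_two_group_effect()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  cohort <- sim$cohort
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (m in cohort$masks)
    write_mask(m, file.path(dir, "masks", paste0(m$subject_id, ".nii.gz")))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  if (!is.null(sim$risk_field))
    write_mask(sim$risk_field, file.path(dir, "risk_field.nii.gz"),
               grid = cohort$grid, datatype = "float")
  if (!is.null(sim$params)) {
    pl <- unclass(sim$params)
    pl$centre_means <- lapply(pl$centre_means, as.numeric)
    yaml::write_yaml(pl, file.path(dir, "params.yaml"))
  }
  invisible(dir)
}

#' Read a cohort fixture written by [write_fixture()] (or arranged likewise)
#'
#' @param dir directory containing `masks/*.nii(.gz)` and `clinical.csv`.
#' @return a `glioma_cohort`.
#' @export
read_cohort <- function(dir) {
  mask_files <- list.files(file.path(dir, "masks"),
                           pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (length(mask_files) == 0L) stop("no masks found under ", dir, "/masks")
  masks <- lapply(mask_files, read_mask)
  clinical <- read_clinical(file.path(dir, "clinical.csv"))
  assemble_cohort(masks, clinical)
}
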