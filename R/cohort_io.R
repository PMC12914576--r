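#' @keywords internal
"_PACKAGE"

## ---- grid helpers (internal) -------------------------------------------

new_grid <- function(shape, voxel_size, affine) {
  stopifnot(length(shape) == 3L, all(shape > 0),
            length(voxel_size) == 3L, all(voxel_size > 0),
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(shape = as.integer(shape),
                 voxel_size = as.numeric(voxel_size),
                 affine = unname(affine)),
            class = "lesion_grid")
}

default_affine <- function(shape, voxel_size) {
  # voxel-to-world map placing the grid centre at the world origin
  aff <- diag(c(voxel_size, 1))
  aff[1:3, 4] <- -voxel_size * (shape - 1) / 2
  aff
}

grids_equal <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

voxel_volume_mm3 <- function(grid) prod(grid$voxel_size)

## ---- MaskVolume ---------------------------------------------------------

#' Construct a binary lesion mask volume
#'
#' A `mask_volume` holds one subject's binary tumour segmentation on the
#' cohort's common voxel grid, together with the voxel size (mm) and the
#' 4x4 voxel-to-world affine. Values are strictly 0/1; multi-compartment
#' label maps (enhancing core, necrosis, oedema coded as 1, 2, 3, ...) are
#' collapsed to any-nonzero so that all subjects contribute a single
#' whole-tumour mask.
#'
#' @param data 3-D numeric or logical array; anything `> 0.5` becomes lesion.
#' @param subject_id character scalar identifying the subject.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param affine 4x4 voxel(0-based)-to-world transform; defaults to a
#'   centred axis-aligned grid.
#' @return An object of class `mask_volume` with fields `subject_id`,
#'   `data` (integer 0/1 array), `shape`, `voxel_size`, `affine`.
#' @export
mask_volume <- function(data, subject_id, voxel_size = c(1, 1, 1),
                        affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("mask data must be a 3-D array, got ", length(dim(data)), " dimensions")
  shape <- dim(data)
  if (is.null(affine)) affine <- default_affine(shape, voxel_size)
  bin <- array(as.integer(data > 0.5), dim = shape)
  if (sum(bin) == 0L)
    warning("mask for subject '", subject_id, "' is empty (no lesion voxels); ",
            "subject is excludable", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 data = bin,
                 shape = as.integer(shape),
                 voxel_size = as.numeric(voxel_size),
                 affine = unname(as.matrix(affine))),
            class = "mask_volume")
}

mask_grid <- function(mask) new_grid(mask$shape, mask$voxel_size, mask$affine)

#' Read a binary tumour mask from a NIfTI-1 file
#'
#' Loads a NIfTI volume and binarizes it at 0.5 (`data > 0.5`), so integer
#' label maps and probabilistic segmentations are both accepted. The subject
#' identifier defaults to the filename stem.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3-D volume.
#' @param subject_id optional identifier; default strips directory and
#'   `.nii`/`.nii.gz` extension from `path`.
#' @return A [mask_volume()].
#' @export
read_mask <- function(path, subject_id = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3-D NIfTI volume, got ", length(d), "-D: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  mask_volume(array(as.numeric(img), dim = d), subject_id,
              voxel_size = RNifti::pixdim(img)[1:3],
              affine = unname(RNifti::xform(img)))
}

#' Write a mask (or any 3-D map) as NIfTI-1
#'
#' @param x a `mask_volume`, or a 3-D array (then `grid` is required).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param grid a grid (from a cohort or mask) when `x` is a bare array.
#' @param datatype NIfTI storage type, e.g. `"int32"` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(x, path, grid = NULL, datatype = "int32") {
  if (inherits(x, "mask_volume")) {
    grid <- mask_grid(x)
    arr <- x$data
  } else {
    if (is.null(grid)) stop("writing a bare array requires `grid`")
    arr <- x
  }
  img <- RNifti::asNifti(arr, datatype = datatype)
  # voxel size is implied by the qform scales; set both xforms explicitly
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Tumour volume of a mask in millilitres
#'
#' Nonzero-voxel count times the voxel volume (product of voxel edge
#' lengths, mm^3), divided by 1000.
#'
#' @param mask a [mask_volume()].
#' @return volume in ml.
#' @export
compute_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$data) * prod(mask$voxel_size) / 1000
}

## ---- ClinicalTable ------------------------------------------------------

clinical_columns <- c("subject_id", "age_years", "sex", "os_days",
                      "volume_ml", "idh", "mgmt", "codel_1p19q")

clinical_levels <- list(
  sex = c("female", "male"),
  idh = c("wildtype", "mutant"),
  mgmt = c("methylated", "unmethylated"),
  codel_1p19q = c("codeleted", "non_codeleted")
)

#' Validate a clinical table
#'
#' Checks column names and types, enforces unique subject ids, and flags
#' (without erroring) rows carrying a 1p/19q co-deletion label while not
#' IDH-mutant, where the label is not biologically meaningful. Missing
#' values are explicit `NA`, never 0.
#'
#' @param df data frame with columns `subject_id, age_years, sex, os_days,
#'   volume_ml, idh, mgmt, codel_1p19q` (extra columns are kept).
#' @return the validated data frame (factors with canonical levels), of
#'   class `clinical_table`/`data.frame`.
#' @export
clinical_table <- function(df) {
  missing_cols <- setdiff(clinical_columns, names(df))
  if (length(missing_cols))
    stop("clinical table missing columns: ", paste(missing_cols, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in clinical table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  for (col in c("age_years", "os_days", "volume_ml"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in names(clinical_levels)) {
    v <- as.character(df[[col]])
    v[!is.na(v) & v == ""] <- NA
    bad <- !is.na(v) & !(v %in% clinical_levels[[col]])
    if (any(bad))
      stop("invalid values in '", col, "': ", paste(unique(v[bad]), collapse = ", "))
    df[[col]] <- factor(v, levels = clinical_levels[[col]])
  }
  if (any(!is.na(df$age_years) & df$age_years < 0)) stop("negative age_years")
  if (any(!is.na(df$os_days) & df$os_days < 0)) stop("negative os_days")
  odd_codel <- !is.na(df$codel_1p19q) & (is.na(df$idh) | df$idh != "mutant")
  if (any(odd_codel))
    warning(sum(odd_codel), " subject(s) carry a 1p19q label without IDH-mutant ",
            "status; label kept but flagged", call. = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical CSV
#'
#' Expects the exact header
#' `subject_id,age_years,sex,os_days,volume_ml,idh,mgmt,codel_1p19q`;
#' empty cells are missing values.
#'
#' @param path CSV path.
#' @return a validated [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  if (!identical(names(df)[seq_along(clinical_columns)], clinical_columns))
    stop("clinical CSV header must start with: ",
         paste(clinical_columns, collapse = ","))
  clinical_table(df)
}

#' Write a clinical table as CSV (empty cell = missing)
#' @param clinical a [clinical_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, na = "")
  invisible(path)
}

## ---- Cohort -------------------------------------------------------------

#' Assemble a cohort of masks and clinical rows on one common grid
#'
#' Inner-joins masks and clinical rows on `subject_id`; subjects present on
#' only one side are dropped and reported (attribute `"dropped"` plus a
#' message). All masks must share one grid (identical shape; voxel size and
#' affine equal within absolute tolerance 1e-4). Missing `volume_ml` entries
#' are filled from the masks.
#'
#' @param masks list of [mask_volume()] objects.
#' @param clinical a [clinical_table()] (or coercible data frame).
#' @return object of class `glioma_cohort`: list with `masks` (named list),
#'   `clinical` (rows aligned to masks), `grid`, and attribute `dropped`.
#' @export
assemble_cohort <- function(masks, clinical) {
  if (length(masks) == 0L) stop("no masks supplied")
  if (!inherits(clinical, "clinical_table")) clinical <- clinical_table(clinical)
  if (nrow(clinical) == 0L) stop("empty clinical table")
  ids <- vapply(masks, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    stop("duplicate mask subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(masks) <- ids
  grid <- mask_grid(masks[[1]])
  ok <- vapply(masks, function(m) grids_equal(mask_grid(m), grid), logical(1))
  if (!all(ok))
    stop("masks not on the common grid: ", paste(ids[!ok], collapse = ", "))

  keep <- intersect(ids, clinical$subject_id)
  if (length(keep) == 0L) stop("no subjects shared between masks and clinical table")
  dropped <- list(mask_only = setdiff(ids, keep),
                  clinical_only = setdiff(clinical$subject_id, keep))
  n_drop <- length(dropped$mask_only) + length(dropped$clinical_only)
  if (n_drop > 0)
    message("assemble_cohort: dropped ", n_drop, " unmatched subject(s) (",
            length(dropped$mask_only), " mask-only, ",
            length(dropped$clinical_only), " clinical-only)")
  keep <- sort(keep)
  masks <- masks[keep]
  clin <- clinical[match(keep, clinical$subject_id), , drop = FALSE]
  rownames(clin) <- NULL
  fill <- is.na(clin$volume_ml)
  if (any(fill))
    clin$volume_ml[fill] <- vapply(masks[fill], compute_volume_ml, numeric(1))
  structure(list(masks = masks, clinical = clin, grid = grid),
            class = "glioma_cohort", dropped = dropped)
}

#' Number of subjects in a cohort
#' @param cohort a `glioma_cohort`.
#' @return integer count.
#' @export
n_subjects <- function(cohort) length(cohort$masks)

cohort_ids <- function(cohort) names(cohort$masks)

## Subject-by-voxel lesion matrix (V x n, double). Column order follows
## `subject_ids` (default: all). Memory is the price of vectorized per-voxel
## statistics; a 32^3 grid with n = 400 is ~100 MB transiently.
lesion_matrix <- function(cohort, subject_ids = NULL) {
  if (is.null(subject_ids)) subject_ids <- cohort_ids(cohort)
  missing_ids <- setdiff(subject_ids, cohort_ids(cohort))
  if (length(missing_ids))
    stop("unknown subject_id: ", paste(missing_ids, collapse = ", "))
  V <- prod(cohort$grid$shape)
  X <- matrix(0, nrow = V, ncol = length(subject_ids))
  for (j in seq_along(subject_ids))
    X[, j] <- as.numeric(cohort$masks[[subject_ids[j]]]$data)
  colnames(X) <- subject_ids
  X
}

#' Subset a cohort by subject id
#' @param cohort a `glioma_cohort`.
#' @param subject_ids ids to keep (order preserved).
#' @return a `glioma_cohort`.
#' @export
subset_cohort <- function(cohort, subject_ids) {
  missing_ids <- setdiff(subject_ids, cohort_ids(cohort))
  if (length(missing_ids))
    stop("unknown subject_id: ", paste(missing_ids, collapse = ", "))
  clin <- cohort$clinical[match(subject_ids, cohort$clinical$subject_id), ,
                          drop = FALSE]
  rownames(clin) <- NULL
  structure(list(masks = cohort$masks[subject_ids], clinical = clin,
                 grid = cohort$grid),
            class = "glioma_cohort")
}

## ---- AtlasVolume --------------------------------------------------------

#' Construct an integer-labelled atlas on a cohort grid
#'
#' Label 0 is reserved for background; at least one nonzero label must be
#' present.
#'
#' @param data 3-D array of nonnegative integer labels.
#' @param label_names named character vector mapping label (as name) to
#'   region name; labels without a name get `"roi_<label>"`.
#' @param voxel_size,affine grid geometry (as for [mask_volume()]).
#' @return object of class `atlas_volume`.
#' @export
atlas_volume <- function(data, label_names = NULL, voxel_size = c(1, 1, 1),
                         affine = NULL) {
  if (length(dim(data)) != 3L) stop("atlas must be a 3-D array")
  lab <- as.integer(round(data))
  if (any(lab < 0)) stop("atlas labels must be nonnegative integers")
  data <- array(lab, dim = dim(data))
  labels <- sort(setdiff(unique(lab), 0L))
  if (length(labels) == 0L) stop("atlas has no nonzero labels")
  nm <- stats::setNames(paste0("roi_", labels), as.character(labels))
  if (!is.null(label_names)) {
    keep <- intersect(names(label_names), names(nm))
    nm[keep] <- label_names[keep]
  }
  if (is.null(affine)) affine <- default_affine(dim(data), voxel_size)
  structure(list(data = data, labels = labels, label_names = nm,
                 shape = as.integer(dim(data)),
                 voxel_size = as.numeric(voxel_size),
                 affine = unname(as.matrix(affine))),
            class = "atlas_volume")
}

#' Read an integer-labelled atlas NIfTI plus optional label-name CSV
#'
#' @param path atlas NIfTI path.
#' @param labels_csv optional two-column CSV `label,name`.
#' @return an [atlas_volume()].
#' @export
read_atlas <- function(path, labels_csv = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("atlas must be a 3-D NIfTI volume")
  nm <- NULL
  if (!is.null(labels_csv)) {
    tab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
    if (!all(c("label", "name") %in% names(tab)))
      stop("labels CSV must have columns label,name")
    nm <- stats::setNames(as.character(tab$name), as.character(tab$label))
  }
  atlas_volume(array(as.numeric(img), dim = dim(img)), label_names = nm,
               voxel_size = RNifti::pixdim(img)[1:3],
               affine = unname(RNifti::xform(img)))
}

#' Synthetic octant atlas
#'
#' Partitions the grid into its 8 octants (labels 1-8), a stand-in for a
#' parcellation atlas in tests and examples. It is synthetic: it does not
#' correspond to any anatomical parcellation.
#'
#' @param grid a grid, e.g. `cohort$grid`.
#' @return an [atlas_volume()] on that grid.
#' @export
octant_atlas <- function(grid) {
  s <- grid$shape
  ix <- slice.index(array(0L, s), 1) > ceiling(s[1] / 2)
  iy <- slice.index(array(0L, s), 2) > ceiling(s[2] / 2)
  iz <- slice.index(array(0L, s), 3) > ceiling(s[3] / 2)
  lab <- 1L + ix + 2L * iy + 4L * iz
  nm <- stats::setNames(
    paste0("octant_",
           c("imimim", "ipimim", "imipim", "ipipim",
             "imimip", "ipimip", "imipip", "ipipip")),
    as.character(1:8))
  atlas_volume(lab, label_names = nm, voxel_size = grid$voxel_size,
               affine = grid$affine)
}
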