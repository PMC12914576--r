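## Voxel-wise lesion frequency (sum) maps and volume tertiles.

#' Voxel-wise lesion frequency map
#'
#' Adds up the binary tumour masks of a subject subset: `counts[v]` is the
#' number of subset subjects whose lesion covers voxel `v`, and `percent`
#' expresses the same as `100 * counts / n`.
#'
#' @param cohort a `glioma_cohort`.
#' @param subject_ids optional character vector of subjects to aggregate
#'   (default: all). Unknown ids are an error.
#' @param label free-text label of the subset (stored in the result).
#' @return object of class `frequency_map`: list with `counts` (integer 3-D
#'   array), `percent` (float 3-D array), `n`, `subset_label`, `grid`.
#' @export
sum_map <- function(cohort, subject_ids = NULL, label = "all") {
  stopifnot(inherits(cohort, "glioma_cohort"))
  if (is.null(subject_ids)) subject_ids <- cohort_ids(cohort)
  if (length(subject_ids) == 0L) stop("empty subject subset")
  missing_ids <- setdiff(subject_ids, cohort_ids(cohort))
  if (length(missing_ids))
    stop("unknown subject_id: ", paste(missing_ids, collapse = ", "))
  counts <- array(0L, dim = cohort$grid$shape)
  for (id in subject_ids) counts <- counts + cohort$masks[[id]]$data
  n <- length(subject_ids)
  structure(list(counts = counts, percent = 100 * counts / n, n = n,
                 subset_label = label, grid = cohort$grid),
            class = "frequency_map")
}

#' Split tumour volumes into tertiles
#'
#' Cutoffs are the 1/3 and 2/3 empirical quantiles (linear-interpolation
#' definition, `stats::quantile` type 7). Labels follow the convention of
#' the printed ranges `<q1`, `q1..q2`, `>q2`: a volume exactly equal to a
#' cutoff is `medium` (both boundaries inclusive).
#'
#' @param volumes named numeric vector, subject id -> volume (ml).
#' @return object of class `tertile_assignment`: list with `cutoffs`
#'   (`c(q1, q2)`), `labels` (named factor small/medium/large), `sizes`.
#' @export
tertile_split <- function(volumes) {
  if (length(volumes) < 3L) stop("need at least 3 volumes for tertiles")
  if (is.null(names(volumes))) stop("volumes must be named by subject_id")
  if (anyNA(volumes)) stop("missing volumes")
  if (max(volumes) == min(volumes))
    stop("all volumes identical; tertiles undefined")
  q <- stats::quantile(volumes, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  lab <- ifelse(volumes < q[1], "small",
                ifelse(volumes > q[2], "large", "medium"))
  lab <- factor(lab, levels = c("small", "medium", "large"))
  names(lab) <- names(volumes)
  structure(list(cutoffs = c(q1_ml = q[1], q2_ml = q[2]),
                 labels = lab,
                 sizes = table(lab)),
            class = "tertile_assignment")
}

#' Frequency maps for the three volume tertiles
#'
#' @param cohort a `glioma_cohort`.
#' @return named list of three [sum_map()] results (`small`, `medium`,
#'   `large`), with the `tertile_assignment` attached as attribute
#'   `"tertiles"`.
#' @export
tertile_maps <- function(cohort) {
  vols <- stats::setNames(cohort$clinical$volume_ml, cohort$clinical$subject_id)
  tert <- tertile_split(vols)
  maps <- lapply(levels(tert$labels), function(lv)
    sum_map(cohort, names(tert$labels)[tert$labels == lv],
            label = paste0("volume_", lv)))
  names(maps) <- levels(tert$labels)
  attr(maps, "tertiles") <- tert
  maps
}

#' Frequency maps per level of a clinical factor or binned attribute
#'
#' For factors (`idh`, `mgmt`, `codel_1p19q`, `sex`) one map per level over
#' complete cases. For `age_years`, decade bins `[10k, 10k + 10)`; for
#' `os_days`, bins in months (default cutpoints 6, 12, 18 months, i.e. the
#' four bands shorter than 6 months up to longer than 18 months).
#'
#' @param cohort a `glioma_cohort`.
#' @param attribute one of `idh`, `mgmt`, `codel_1p19q`, `sex`, `age_years`,
#'   `os_days`.
#' @param os_cut_months cutpoints (months) for survival bands.
#' @return named list of `frequency_map`s (levels with no subjects are
#'   dropped).
#' @export
subgroup_maps <- function(cohort, attribute,
                          os_cut_months = c(6, 12, 18)) {
  clin <- cohort$clinical
  if (!attribute %in% names(clin)) stop("unknown attribute: ", attribute)
  x <- clin[[attribute]]
  if (attribute == "age_years") {
    g <- factor(paste0("age_", 10 * (x %/% 10), "s"))
  } else if (attribute == "os_days") {
    cuts <- c(0, os_cut_months * 30.44, Inf)
    lab <- c(paste0("os_lt_", os_cut_months[1], "mo"),
             paste0("os_", utils::head(os_cut_months, -1), "_",
                    utils::tail(os_cut_months, -1), "mo"),
             paste0("os_gt_", utils::tail(os_cut_months, 1), "mo"))
    g <- cut(x, breaks = cuts, labels = lab, right = FALSE)
  } else if (is.factor(x)) {
    g <- x
  } else stop("attribute '", attribute, "' is not a factor or binnable")
  keep <- !is.na(g)
  maps <- list()
  for (lv in levels(droplevels(g[keep]))) {
    ids <- clin$subject_id[keep & g == lv]
    if (length(ids))
      maps[[lv]] <- sum_map(cohort, ids, label = paste0(attribute, "_", lv))
  }
  maps
}

#' Write a frequency map as a NIfTI pair (counts int32, percent float32)
#'
#' @param fmap a `frequency_map`.
#' @param prefix output path prefix; writes `<prefix>_counts.nii.gz` and
#'   `<prefix>_percent.nii.gz`.
#' @return the two paths, invisibly.
#' @export
write_frequency_map <- function(fmap, prefix) {
  p1 <- paste0(prefix, "_counts.nii.gz")
  p2 <- paste0(prefix, "_percent.nii.gz")
  write_mask(fmap$counts, p1, grid = fmap$grid, datatype = "int32")
  write_mask(fmap$percent, p2, grid = fmap$grid, datatype = "float")
  invisible(c(p1, p2))
}
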