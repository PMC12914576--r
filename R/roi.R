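## Atlas-based ROI lesion load and per-ROI subgroup tests.

#' Per-subject lesion load within each atlas ROI
#'
#' `load(i, r) = |mask_i intersect ROI_r| / |ROI_r|`: the fraction of the
#' ROI's voxels lesioned by that subject. This definition is invariant to
#' tumour size differences within a region; the alternative normalization by
#' tumour size (fraction of the tumour falling in the ROI) is available via
#' `normalize = "tumour"`.
#'
#' @param cohort a `glioma_cohort`.
#' @param atlas an [atlas_volume()] on the cohort grid.
#' @param normalize `"roi"` (default) or `"tumour"`.
#' @return numeric matrix, subjects x ROIs, entries in [0, 1]; ROI labels as
#'   column names, attribute `"n_voxels"` carries ROI sizes.
#' @export
roi_load <- function(cohort, atlas, normalize = c("roi", "tumour")) {
  stopifnot(inherits(cohort, "glioma_cohort"), inherits(atlas, "atlas_volume"))
  normalize <- match.arg(normalize)
  if (!grids_equal(new_grid(atlas$shape, atlas$voxel_size, atlas$affine),
                   cohort$grid))
    stop("atlas grid does not match cohort grid")
  lab <- as.vector(atlas$data)
  labels <- atlas$labels
  ids <- cohort_ids(cohort)
  out <- matrix(0, nrow = length(ids), ncol = length(labels),
                dimnames = list(ids, as.character(labels)))
  roi_idx <- lapply(labels, function(l) which(lab == l))
  roi_n <- vapply(roi_idx, length, integer(1))
  for (i in seq_along(ids)) {
    m <- as.vector(cohort$masks[[ids[i]]]$data)
    inter <- vapply(roi_idx, function(ix) sum(m[ix]), numeric(1))
    out[i, ] <- if (normalize == "roi") inter / roi_n
    else inter / max(sum(m), 1)
  }
  attr(out, "n_voxels") <- stats::setNames(roi_n, as.character(labels))
  attr(out, "normalize") <- normalize
  out
}

#' Per-ROI association between lesion load and a binary subgroup
#'
#' For each ROI, a univariate logistic regression of the class on the ROI
#' load (Wald z and two-sided p), with BH-FDR across the atlas's testable
#' ROIs. ROIs with constant load, or where the fit separates or fails to
#' converge, are flagged untestable and excluded from the BH family.
#'
#' @param loads matrix from [roi_load()].
#' @param group binary factor (or 2-level vector) aligned with the rows of
#'   `loads`; the second level is class 1.
#' @param atlas optional [atlas_volume()] supplying ROI names.
#' @return data frame of class `roi_table`: one row per ROI with `label`,
#'   `name`, `n_voxels`, mean load per class, `z`, `p`, `q`, `testable`.
#' @export
roi_group_test <- function(loads, group, atlas = NULL) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("group must be binary")
  keep <- !is.na(g)
  if (sum(keep) < 4L) stop("too few complete cases")
  g01 <- as.integer(g[keep]) - 1L
  if (sum(g01 == 0L) < 2L || sum(g01 == 1L) < 2L)
    stop("each class needs at least 2 members")
  L <- loads[keep, , drop = FALSE]
  labels <- colnames(loads)
  nm <- if (!is.null(atlas)) atlas$label_names[labels] else paste0("roi_", labels)
  nv <- attr(loads, "n_voxels")
  res <- data.frame(label = as.integer(labels), name = unname(nm),
                    n_voxels = if (!is.null(nv)) unname(nv[labels]) else NA_integer_,
                    mean_load_class0 = colMeans(L[g01 == 0L, , drop = FALSE]),
                    mean_load_class1 = colMeans(L[g01 == 1L, , drop = FALSE]),
                    z = NA_real_, p = NA_real_, q = NA_real_,
                    testable = TRUE, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (j in seq_along(labels)) {
    x <- L[, j]
    if (stats::sd(x) == 0) { res$testable[j] <- FALSE; next }
    fit <- tryCatch(
      withCallingHandlers(
        stats::glm(g01 ~ x, family = stats::binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                    conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged ||
        summary(fit)$coefficients["x", "Std. Error"] > 1e3) {
      res$testable[j] <- FALSE
      next
    }
    co <- summary(fit)$coefficients
    res$z[j] <- co["x", "z value"]
    res$p[j] <- co["x", "Pr(>|z|)"]
  }
  tst <- res$testable
  res$q[tst] <- fdr_adjust(res$p[tst])
  class(res) <- c("roi_table", "data.frame")
  res
}

#' Write an ROI table as TSV
#' @param roi_table result of [roi_group_test()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(roi_table, path) {
  utils::write.table(roi_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
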