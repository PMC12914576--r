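## Print and summary methods.

#' @export
print.mask_volume <- function(x, ...) {
  cat("<mask_volume> subject", x$subject_id, "\n")
  cat("  grid ", paste(x$shape, collapse = "x"), ", voxels ",
      paste(x$voxel_size, collapse = "x"), " mm\n", sep = "")
  cat("  lesion voxels:", sum(x$data),
      sprintf("(%.3f ml)\n", compute_volume_ml(x)))
  invisible(x)
}

#' @export
print.glioma_cohort <- function(x, ...) {
  cat("<glioma_cohort> n =", n_subjects(x), "subjects\n")
  cat("  grid ", paste(x$grid$shape, collapse = "x"), ", voxels ",
      paste(x$grid$voxel_size, collapse = "x"), " mm\n", sep = "")
  vols <- x$clinical$volume_ml
  cat(sprintf("  volume_ml: median %.1f [%.1f, %.1f]\n",
              stats::median(vols), min(vols), max(vols)))
  for (col in c("idh", "mgmt", "codel_1p19q", "sex")) {
    tab <- table(x$clinical[[col]])
    if (sum(tab) > 0)
      cat("  ", col, ": ", paste(names(tab), tab, sep = "=", collapse = ", "),
          " (missing ", sum(is.na(x$clinical[[col]])), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.glioma_cohort <- function(object, ...) {
  print(object)
  cat("clinical completeness:\n")
  for (col in setdiff(names(object$clinical), "subject_id"))
    cat(sprintf("  %-12s n = %d\n", col, sum(!is.na(object$clinical[[col]]))))
  invisible(object)
}

#' @export
print.frequency_map <- function(x, ...) {
  cat("<frequency_map> subset '", x$subset_label, "', n = ", x$n, "\n", sep = "")
  cat(sprintf("  peak overlap: %d subjects (%.1f%%) at voxel [%s]\n",
              max(x$counts), max(x$percent),
              paste(which(x$counts == max(x$counts), arr.ind = TRUE)[1, ] - 1,
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", x$kind, "-map of '", x$attribute, "', n_used = ",
      x$n_used, if (x$kind == "t") paste0(", df = ", x$df), "\n", sep = "")
  cat("  valid voxels:", sum(x$valid),
      "| separated/non-converged:", x$n_invalid_separation, "\n")
  if (any(x$valid))
    cat(sprintf("  stat range: [%.2f, %.2f]; min q = %.3g\n",
                min(x$stat[x$valid]), max(x$stat[x$valid]),
                min(x$q[x$valid])))
  invisible(x)
}

#' @export
print.thresholded_map <- function(x, ...) {
  cat("<thresholded_map> ", x$kind, "-map of '", x$attribute, "', ",
      x$method, " alpha = ", x$alpha, ": ", x$n_voxels,
      " significant voxel(s)\n", sep = "")
  invisible(x)
}

#' @export
print.tertile_assignment <- function(x, ...) {
  cat(sprintf("<tertile_assignment> cutoffs %.1f / %.1f ml; sizes %s\n",
              x$cutoffs[1], x$cutoffs[2],
              paste(names(x$sizes), as.integer(x$sizes), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f (n_pos = %d, n_neg = %d)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ..., add = FALSE) {
  if (!add) {
    plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "False positive rate", ylab = "True positive rate", ...)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  } else graphics::lines(x$fpr, x$tpr, ...)
  invisible(x)
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("<delong_test> AUC %.3f vs %.3f; Z = %.2f, p = %.3g (n = %d)\n",
              x$auc_a, x$auc_b, x$z, x$p_two_sided, x$n))
  invisible(x)
}

#' @export
print.survival_report <- function(x, ...) {
  cat("<survival_report> eval =", x$eval, ", n_used =", x$n_used,
      ", cutoff =", x$cutoff_days, "days\n")
  for (nm in names(x$auc))
    cat(sprintf("  AUC %-12s = %.3f\n", nm, x$auc[nm]))
  for (nm in names(x$delong)) {
    d <- x$delong[[nm]]
    cat(sprintf("  DeLong %s: Z = %.2f, p = %.3g\n", nm, d$z, d$p_two_sided))
  }
  invisible(x)
}

#' @export
print.synth_params <- function(x, ...) {
  cat("<synth_params> n =", x$n_subjects, "on grid",
      paste(x$grid_shape, collapse = "x"), "\n")
  cat("  groups:", paste(names(x$group_fracs), x$group_fracs, sep = "=",
                         collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat("<atlas_volume>", length(x$labels), "ROI(s) on grid",
      paste(x$shape, collapse = "x"), "\n")
  invisible(x)
}
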