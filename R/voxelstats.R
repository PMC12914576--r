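## Mass-univariate per-voxel statistics.
##
## At every analysable voxel an independent model relates the subject-level
## attribute (response) to the binary lesion indicator at that voxel
## (predictor); correction across voxels is Benjamini-Hochberg FDR. Each
## attribute is analysed in its own model with no covariates.

#' Voxels with enough lesioned and non-lesioned subjects for a per-voxel fit
#'
#' A voxel is analysable when at least `min_count` subjects carry a lesion
#' there AND at least `min_count` do not; voxels lesioned in (almost) all or
#' (almost) no subjects have no usable variation.
#'
#' @param cohort a `glioma_cohort`.
#' @param min_count minimum group size per side (default 5).
#' @param subject_ids optional subject subset.
#' @return logical 3-D array.
#' @export
coverage_mask <- function(cohort, min_count = 5, subject_ids = NULL) {
  stopifnot(min_count >= 1)
  fm <- sum_map(cohort, subject_ids)
  fm$counts >= min_count & fm$counts <= fm$n - min_count
}

## Internal constructor for stat_map results.
new_stat_map <- function(stat, kind, p, valid, grid, attribute, n_used,
                         df = NA_integer_, n_invalid_separation = 0L,
                         min_count = NA_integer_) {
  q <- array(NA_real_, dim = dim(stat))
  if (any(valid)) q[valid] <- fdr_adjust(p[valid])
  structure(list(stat = stat, kind = kind, df = df, p = p, q = q,
                 valid = valid, attribute = attribute, n_used = n_used,
                 n_invalid_separation = n_invalid_separation,
                 min_count = min_count, grid = grid),
            class = "stat_map")
}

#' Per-voxel linear model of an attribute on lesion presence (t-map)
#'
#' At each analysable voxel `v`, fits `y_i = b0 + b1 * m_iv` by least
#' squares, where `m_iv` is subject i's binary lesion indicator at `v`, over
#' the attribute's complete cases. The t statistic of `b1` with
#' `df = n_used - 2` is algebraically the pooled-variance two-sample t
#' between lesioned and non-lesioned subjects, and is computed in that
#' (vectorized) form. Two-sided p-values from the t distribution; BH-FDR
#' adjusted q-values across the map's valid voxels.
#'
#' @param cohort a `glioma_cohort`.
#' @param attribute continuous attribute column: `volume_ml`, `age_years` or
#'   `os_days`.
#' @param min_count per-side coverage threshold (see [coverage_mask()]).
#' @return a `stat_map` with `kind = "t"`.
#' @export
voxelwise_linear <- function(cohort, attribute = c("volume_ml", "age_years",
                                                   "os_days"),
                             min_count = 5) {
  attribute <- match.arg(attribute)
  clin <- cohort$clinical
  y_all <- clin[[attribute]]
  keep <- !is.na(y_all)
  if (sum(keep) < 3L) stop("attribute '", attribute, "' has <3 complete cases")
  ids <- clin$subject_id[keep]
  y <- y_all[keep]
  X <- lesion_matrix(cohort, ids)          # V x n
  fit <- linear_t_stats(X, y, min_count)
  new_stat_map(array(fit$t, dim = cohort$grid$shape), "t",
               array(fit$p, dim = cohort$grid$shape),
               array(fit$valid, dim = cohort$grid$shape),
               cohort$grid, attribute, n_used = length(y),
               df = length(y) - 2L, min_count = as.integer(min_count))
}

## Pooled two-sample t from per-voxel sufficient statistics: n1/S1/Q1 are the
## lesioned-group count, sum and sum of squares of y per voxel; n/Sy/Qy the
## totals. Vectorized over voxels; shared by the map fit and its jackknife.
t_from_stats <- function(n1, S1, Q1, n, Sy, Qy, min_count) {
  df <- n - 2
  n0 <- n - n1
  S0 <- Sy - S1
  Q0 <- Qy - Q1
  valid <- n1 >= min_count & n0 >= min_count
  m1 <- S1 / n1
  m0 <- S0 / n0
  ss <- (Q1 - S1^2 / pmax(n1, 1)) + (Q0 - S0^2 / pmax(n0, 1))
  sp2 <- pmax(ss, 0) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  diff <- m1 - m0
  tt <- ifelse(se > 0, diff / se, ifelse(abs(diff) < 1e-12, 0, NA_real_))
  valid <- valid & !is.na(tt)
  tt[!valid] <- NA_real_
  list(t = tt, valid = valid, df = df)
}

## Vectorized per-voxel pooled two-sample t from the lesion matrix (V x n)
## and response y. Returns flat vectors over voxels.
linear_t_stats <- function(X, y, min_count) {
  n <- length(y)
  n1 <- as.vector(X %*% rep(1, n))
  S1 <- as.vector(X %*% y)
  Q1 <- as.vector(X %*% y^2)
  fit <- t_from_stats(n1, S1, Q1, n, sum(y), sum(y^2), min_count)
  fit$p <- 2 * stats::pt(-abs(fit$t), fit$df)
  fit$n1 <- n1
  fit
}

#' Per-voxel logistic model of a binary subgroup on lesion presence (z-map)
#'
#' At each analysable voxel, fits `logit P(class = 1 | m_v) = b0 + b1 * m_v`
#' by maximum likelihood (Newton iterations on the per-voxel 2x2 sufficient
#' statistics; score-norm tolerance 1e-8, at most 25 iterations) over the
#' attribute's complete cases. The Wald z of `b1` with two-sided normal
#' p-values is reported. Voxels with complete or quasi-complete separation
#' (an empty cell in the class-by-lesion table) or non-convergence are
#' marked invalid; their count is reported in `n_invalid_separation`.
#'
#' Class 1 is the second factor level (`mutant`, `unmethylated`,
#' `non_codeleted`, `male`); swapping the labels exactly negates the map.
#'
#' @param cohort a `glioma_cohort`.
#' @param group binary factor column: `idh`, `mgmt`, `codel_1p19q` or `sex`.
#' @param min_count per-side coverage threshold (see [coverage_mask()]).
#' @return a `stat_map` with `kind = "z"`.
#' @export
voxelwise_logistic <- function(cohort, group = c("idh", "mgmt", "codel_1p19q",
                                                 "sex"),
                               min_count = 5) {
  group <- match.arg(group)
  clin <- cohort$clinical
  g_all <- clin[[group]]
  keep <- !is.na(g_all)
  g <- as.integer(g_all[keep]) - 1L     # second level = class 1
  if (sum(g == 0L) < 2L || sum(g == 1L) < 2L)
    stop("group '", group, "' needs at least 2 complete cases per class")
  ids <- clin$subject_id[keep]
  X <- lesion_matrix(cohort, ids)
  n <- length(g)
  n1v <- as.vector(X %*% rep(1, n))     # lesioned subjects per voxel
  y1v <- as.vector(X %*% g)             # of those, class 1
  n0v <- n - n1v
  y0v <- sum(g) - y1v
  covered <- n1v >= min_count & n0v >= min_count
  sep <- covered & (y1v == 0 | y1v == n1v | y0v == 0 | y0v == n0v)
  fit_idx <- which(covered & !sep)
  fit <- logistic_wald_2x2(n0v[fit_idx], y0v[fit_idx],
                           n1v[fit_idx], y1v[fit_idx])
  z <- rep(NA_real_, length(n1v))
  z[fit_idx] <- fit$z
  nonconv <- fit_idx[!fit$converged]
  z[nonconv] <- NA_real_
  valid <- !is.na(z)
  p <- 2 * stats::pnorm(-abs(z))
  shape <- cohort$grid$shape
  new_stat_map(array(z, dim = shape), "z", array(p, dim = shape),
               array(valid, dim = shape), cohort$grid, group,
               n_used = n,
               n_invalid_separation = sum(sep) + length(nonconv),
               min_count = as.integer(min_count))
}

## Newton-Raphson ML fit of logit P(y=1) = b0 + b1*m for grouped binomial
## data with m in {0,1}, vectorized across voxels. Inputs are per-voxel cell
## counts: n0/y0 for non-lesioned, n1/y1 for lesioned subjects. Returns the
## Wald z of b1 and a convergence flag.
logistic_wald_2x2 <- function(n0, y0, n1, y1, tol = 1e-8, max_iter = 25L) {
  k <- length(n0)
  if (k == 0L) return(list(z = numeric(0), converged = logical(0)))
  ybar <- (y0 + y1) / (n0 + n1)
  b0 <- stats::qlogis(pmin(pmax(ybar, 1e-6), 1 - 1e-6))
  b1 <- rep(0, k)
  converged <- rep(FALSE, k)
  for (it in seq_len(max_iter)) {
    p0 <- stats::plogis(b0)
    p1 <- stats::plogis(b0 + b1)
    s0 <- (y0 - n0 * p0) + (y1 - n1 * p1)   # dl/db0
    s1 <- y1 - n1 * p1                      # dl/db1
    converged <- converged | (pmax(abs(s0), abs(s1)) < tol)
    if (all(converged)) break
    w0 <- n0 * p0 * (1 - p0)
    w1 <- n1 * p1 * (1 - p1)
    det <- w0 * w1                          # det of [[w0+w1, w1],[w1, w1]]
    act <- !converged & det > 0
    d0 <- (w1 * s0 - w1 * s1) / det         # H^-1 %*% score, closed form
    d1 <- (-w1 * s0 + (w0 + w1) * s1) / det
    b0[act] <- b0[act] + d0[act]
    b1[act] <- b1[act] + d1[act]
  }
  p0 <- stats::plogis(b0)
  p1 <- stats::plogis(b0 + b1)
  w0 <- n0 * p0 * (1 - p0)
  w1 <- n1 * p1 * (1 - p1)
  se <- sqrt((w0 + w1) / (w0 * w1))        # [H^-1]_{b1,b1}
  list(z = b1 / se, converged = converged)
}

#' Two-sided critical t value
#'
#' The value `t*` with `P(|T_df| >= t*) = alpha`; e.g. 3.29 at
#' `alpha = 0.001` and 1.96 at `alpha = 0.05` for large df.
#'
#' @param alpha two-sided significance level in (0, 1].
#' @param df degrees of freedom (>= 1).
#' @return critical value (0 when `alpha = 1`).
#' @export
critical_t <- function(alpha, df) {
  stopifnot(alpha > 0, alpha <= 1, df >= 1)
  stats::qt(1 - alpha / 2, df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_{j>=i} (m * p_(j) / j)` capped at 1,
#' returned in the input order (wraps `stats::p.adjust(method = "BH")`).
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Threshold a statistic map
#'
#' @param statmap a `stat_map`.
#' @param alpha significance level.
#' @param method `"uncorrected"` thresholds raw p-values (`p < alpha`);
#'   `"fdr"` thresholds BH-adjusted q-values (`q < alpha`). Both are
#'   intersected with the map's valid voxels.
#' @return object of class `thresholded_map`: list with `mask` (logical 3-D
#'   array), `alpha`, `method`, `attribute`, `kind`, `n_voxels`.
#' @export
threshold_map <- function(statmap, alpha, method = c("uncorrected", "fdr")) {
  stopifnot(inherits(statmap, "stat_map"))
  method <- match.arg(method)
  src <- if (method == "fdr") {
    if (is.null(statmap$q)) stop("stat map carries no q-values for FDR thresholding")
    statmap$q
  } else statmap$p
  mask <- !is.na(src) & src < alpha & statmap$valid
  structure(list(mask = mask, alpha = alpha, method = method,
                 attribute = statmap$attribute, kind = statmap$kind,
                 n_voxels = sum(mask), grid = statmap$grid),
            class = "thresholded_map")
}

#' Write a stat map as NIfTI pair plus a JSON sidecar
#'
#' Emits `<prefix>_stat.nii.gz`, `<prefix>_p.nii.gz` and `<prefix>.json`
#' (kind, df, n_used, attribute, min_count, separation count).
#'
#' @param statmap a `stat_map`.
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_stat_map <- function(statmap, prefix) {
  st <- statmap$stat; st[!statmap$valid] <- 0
  pp <- statmap$p; pp[!statmap$valid] <- 1
  write_mask(st, paste0(prefix, "_stat.nii.gz"), grid = statmap$grid,
             datatype = "float")
  write_mask(pp, paste0(prefix, "_p.nii.gz"), grid = statmap$grid,
             datatype = "float")
  side <- list(kind = statmap$kind, df = statmap$df, n_used = statmap$n_used,
               attribute = statmap$attribute, min_count = statmap$min_count,
               n_invalid_separation = statmap$n_invalid_separation)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}
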