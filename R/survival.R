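## Survival classification from tumour location: overlap of each tumour with
## the voxel-wise survival map as a feature, nested logistic classifiers,
## ROC/AUC, and paired AUC comparison by DeLong's test.

#' Overlap of a tumour with a voxel-wise statistic map
#'
#' The mean of the map's statistic over the subject's lesion voxels
#' restricted to the map's valid voxels (mean rather than sum, so the
#' feature is decorrelated from tumour volume, which enters the comparison
#' as its own model). `statistic = "sum"` gives the volume-coupled variant.
#'
#' @param mask a [mask_volume()] on the map's grid.
#' @param survival_map a `stat_map` (typically the overall-survival t-map).
#' @param statistic `"mean"` (default) or `"sum"`.
#' @return list with `subject_id`, `score` (NA with a warning if the lesion
#'   and the valid region do not intersect) and `n_voxels_used`.
#' @export
overlap_score <- function(mask, survival_map, statistic = c("mean", "sum")) {
  stopifnot(inherits(mask, "mask_volume"), inherits(survival_map, "stat_map"))
  statistic <- match.arg(statistic)
  if (!identical(mask$shape, survival_map$grid$shape))
    stop("mask and map are on different grids")
  sel <- mask$data == 1L & survival_map$valid
  nv <- sum(sel)
  if (nv == 0L) {
    warning("lesion of subject '", mask$subject_id,
            "' does not intersect the map's valid voxels; score missing",
            call. = FALSE)
    score <- NA_real_
  } else {
    vals <- survival_map$stat[sel]
    score <- if (statistic == "mean") mean(vals) else sum(vals)
  }
  list(subject_id = mask$subject_id, score = score, n_voxels_used = nv)
}

#' Dichotomize overall survival at a cutoff
#'
#' `long` if and only if survival strictly exceeds the cutoff (default one
#' year, 365 days); missing survival stays missing and is excluded from
#' modelling.
#'
#' @param os_days numeric vector of survival times (days).
#' @param cutoff_days threshold (default 365).
#' @return factor with levels `short`, `long`.
#' @export
binarize_survival <- function(os_days, cutoff_days = 365) {
  factor(ifelse(os_days > cutoff_days, "long", "short"),
         levels = c("short", "long"))
}

#' Fit a logistic score model and return per-subject risk scores
#'
#' Maximum-likelihood logistic regression of the binary label on the feature
#' columns; the returned scores are the linear predictors, suitable for ROC
#' analysis.
#'
#' @param features numeric matrix or data frame (subjects x features),
#'   complete cases only.
#' @param labels binary factor (second level = positive class).
#' @return numeric vector of linear-predictor scores (attribute
#'   `"coefficients"` carries the fit).
#' @export
fit_score_model <- function(features, labels) {
  X <- as.matrix(features)
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("labels must be binary")
  y <- as.integer(g) - 1L
  if (sum(y == 0L) < 2L || sum(y == 1L) < 2L)
    stop("need at least 2 subjects per class")
  if (anyNA(X) || anyNA(y)) stop("features/labels contain missing values")
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- stats::glm.fit(Xd, y, family = stats::binomial(),
                        control = stats::glm.control(maxit = 100))
  if (!fit$converged)
    stop("logistic score model did not converge (", ncol(X), " features, n = ",
         length(y), ")")
  scores <- as.vector(Xd %*% fit$coefficients)
  attr(scores, "coefficients") <- fit$coefficients
  scores
}

#' ROC curve and AUC with midrank tie handling
#'
#' The AUC is the Mann-Whitney statistic with ties counted 1/2 (midranks);
#' the curve enumerates all unique score thresholds, so it runs from (0, 0)
#' to (1, 1) with nondecreasing FPR/TPR, and its trapezoidal area equals the
#' AUC.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels binary factor/vector; second level is the positive class.
#' @return object of class `roc_curve`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("labels must have exactly 2 levels")
  keep <- !is.na(scores) & !is.na(g)
  scores <- scores[keep]; g <- g[keep]
  y <- as.integer(g) - 1L
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  # curve: classify positive when score >= threshold
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  cum_tp <- cumsum(ys); cum_fp <- cumsum(1 - ys)
  last_of_thr <- cumsum(table(factor(ss, levels = thr))[as.character(thr)])
  tpr <- c(0, cum_tp[last_of_thr] / n1, 1)
  fpr <- c(0, cum_fp[last_of_thr] / n0, 1)
  structure(list(thresholds = c(Inf, thr, -Inf), fpr = unname(fpr),
                 tpr = unname(tpr), auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

## Midrank structural (placement) components of the AUC: V10 over positives,
## V01 over negatives. auc = mean(V10) = mean(V01).
auc_placements <- function(scores, y) {
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0          # P(neg < pos_i), ties 1/2
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1 # P(pos > neg_j), ties 1/2
  list(v10 = v10, v01 = v01)
}

#' Paired comparison of two correlated AUCs (DeLong's test)
#'
#' Both score vectors must refer to the same subjects and labels. Midrank
#' structural components give each model's AUC and the covariance matrix of
#' the pair; the statistic is
#' `z = (auc_a - auc_b) / sqrt(var(auc_a - auc_b))` against a standard
#' normal (two-sided). Runs in O(n log n).
#'
#' @param scores_a,scores_b risk scores of the two models.
#' @param labels binary factor/vector; second level = positive class.
#' @return object of class `delong_test`: list with `auc_a`, `auc_b`,
#'   `var_diff`, `z`, `p_two_sided`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("labels must have exactly 2 levels")
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(g))
    stop("scores_a, scores_b and labels must align subject-by-subject")
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(g)
  a <- scores_a[keep]; b <- scores_b[keep]; y <- as.integer(g[keep]) - 1L
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 subjects per class")
  pa <- auc_placements(a, y)
  pb <- auc_placements(b, y)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (var_diff <= 0) {
    if (abs(auc_a - auc_b) < 1e-12) {
      z <- 0; p <- 1
    } else {
      stop("degenerate DeLong comparison: zero variance with differing AUCs")
    }
  } else {
    z <- (auc_a - auc_b) / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, var_diff = max(var_diff, 0),
                 z = z, p_two_sided = p, n = n1 + n0),
            class = "delong_test")
}

## Overlap features of every subject against the survival map refit without
## subject i: the map's sufficient statistics are downdated in O(V), then all
## n features come from two matrix-vector products (numerator and valid-voxel
## count per lesion).
overlap_features_loo <- function(X, y, i, suff, min_count) {
  m <- X[, i]
  fit <- t_from_stats(suff$n1 - m, suff$S1 - m * y[i], suff$Q1 - m * y[i]^2,
                      suff$n - 1, suff$Sy - y[i], suff$Qy - y[i]^2, min_count)
  t0 <- fit$t
  t0[!fit$valid] <- 0
  num <- as.vector(crossprod(X, t0))
  den <- as.vector(crossprod(X, as.numeric(fit$valid)))
  ifelse(den > 0, num / den, NA_real_)
}

suff_stats <- function(X, y) {
  n <- length(y)
  list(n1 = as.vector(X %*% rep(1, n)),
       S1 = as.vector(X %*% y),
       Q1 = as.vector(X %*% y^2),
       n = n, Sy = sum(y), Qy = sum(y^2))
}

#' Survival classification report: nested models, ROC/AUC, DeLong tests
#'
#' Builds the voxel-wise overall-survival t-map, scores every subject's
#' tumour overlap with it, dichotomizes survival at `cutoff_days`, fits the
#' requested logistic models and compares their ROC curves pairwise with
#' DeLong's test.
#'
#' Evaluation modes: `"in_sample"` fits map and classifiers on all complete
#' cases and scores the same subjects (the overlap feature is then trained
#' on the subjects it is evaluated on — an optimistic, circular estimate,
#' reported because it matches common practice); `"loo"` leave-one-out:
#' each subject's overlap feature comes from a survival map refit without
#' that subject, and each subject's risk score from a classifier refit
#' without that subject.
#'
#' @param cohort a `glioma_cohort`.
#' @param models subset of `"age+overlap"`, `"age+volume"`, `"age"`.
#' @param eval `"in_sample"` (default) or `"loo"`.
#' @param cutoff_days survival dichotomization cutoff (default 365).
#' @param min_count coverage threshold for the survival map.
#' @return object of class `survival_report`: list with `labels`, `scores`
#'   (matrix subjects x models), `roc` (list of `roc_curve`), `auc` (named),
#'   `delong` (list of `delong_test` per model pair), `n_used`, `eval`.
#' @export
survival_roc <- function(cohort,
                         models = c("age+overlap", "age+volume", "age"),
                         eval = c("in_sample", "loo"),
                         cutoff_days = 365, min_count = 5) {
  eval <- match.arg(eval)
  models <- match.arg(models, several.ok = TRUE)
  clin <- cohort$clinical
  keep <- !is.na(clin$os_days) & !is.na(clin$age_years) &
    !is.na(clin$volume_ml)
  if (sum(keep) < 10L) stop("too few complete cases for survival modelling")
  ids <- clin$subject_id[keep]
  os <- clin$os_days[keep]
  age <- clin$age_years[keep]
  vol <- clin$volume_ml[keep]
  labels <- binarize_survival(os, cutoff_days)
  if (length(unique(labels)) < 2L)
    stop("survival cutoff leaves a single class")
  X <- lesion_matrix(cohort, ids)
  n <- length(ids)

  y01 <- as.integer(labels) - 1L
  base_features <- list("age+overlap" = cbind(age = age),
                        "age+volume"  = cbind(age = age, volume = vol),
                        "age"         = cbind(age = age))
  uses_overlap <- vapply(models, function(m) m == "age+overlap", logical(1))
  scores <- matrix(NA_real_, nrow = n, ncol = length(models),
                   dimnames = list(ids, models))

  if (eval == "in_sample") {
    smap <- voxelwise_linear(subset_cohort(cohort, ids), "os_days",
                             min_count = min_count)
    ov <- vapply(ids, function(id)
      overlap_score(cohort$masks[[id]], smap)$score, numeric(1))
    if (anyNA(ov))
      warning(sum(is.na(ov)), " subject(s) have no overlap score (lesion ",
              "outside the map's valid voxels); dropped from modelling",
              call. = FALSE)
    for (mod in models) {
      F <- base_features[[mod]]
      if (uses_overlap[mod]) F <- cbind(F, overlap = ov)
      ok_m <- stats::complete.cases(F)
      scores[ok_m, mod] <- fit_score_model(F[ok_m, , drop = FALSE],
                                           labels[ok_m])
    }
  } else {
    # exact leave-one-out: for held-out subject i the survival map is refit
    # without i, every subject's overlap feature is recomputed against that
    # map, and the classifier is refit on the remaining n - 1 subjects
    suff <- suff_stats(X, os)
    for (i in seq_len(n)) {
      ov_i <- if (any(uses_overlap))
        overlap_features_loo(X, os, i, suff, min_count) else NULL
      for (mod in models) {
        F <- base_features[[mod]]
        if (uses_overlap[mod]) F <- cbind(F, overlap = ov_i)
        Xd <- cbind(1, F)
        if (anyNA(Xd[i, ])) next
        train <- setdiff(which(stats::complete.cases(F)), i)
        fit <- suppressWarnings(
          stats::glm.fit(Xd[train, , drop = FALSE], y01[train],
                         family = stats::binomial()))
        scores[i, mod] <- sum(Xd[i, ] * fit$coefficients)
      }
    }
    if (anyNA(scores))
      warning(sum(apply(is.na(scores), 1, any)),
              " subject(s) lack a score in at least one model (lesion ",
              "outside the map's valid voxels); dropped from its ROC",
              call. = FALSE)
  }

  ok <- stats::complete.cases(scores)
  roc <- lapply(models, function(mod) roc_auc(scores[ok, mod], labels[ok]))
  names(roc) <- models
  auc <- vapply(roc, `[[`, numeric(1), "auc")
  delong <- list()
  if (length(models) > 1L) {
    for (i in seq_len(length(models) - 1L))
      for (j in (i + 1L):length(models)) {
        nm <- paste(models[i], "vs", models[j])
        delong[[nm]] <- delong_compare(scores[ok, models[i]],
                                       scores[ok, models[j]], labels[ok])
      }
  }
  structure(list(labels = labels, scores = scores, roc = roc, auc = auc,
                 delong = delong, n_used = sum(ok), eval = eval,
                 cutoff_days = cutoff_days),
            class = "survival_report")
}
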