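# Overlap scores, ROC/AUC, DeLong comparisons, survival classifiers.

test_that("overlap_score averages the map statistic over lesion∩valid voxels", {
  co <- random_cohort(20, seed = 201)
  sm <- voxelwise_linear(co, "os_days", min_count = 3)
  # constant map over the lesion -> score equals that constant
  cm <- sm
  cm$stat[] <- 3.7
  id <- names(co$masks)[1]
  sc <- overlap_score(co$masks[[id]], cm)
  expect_equal(sc$score, 3.7)
  expect_equal(sc$n_voxels_used, sum(co$masks[[id]]$data == 1L & cm$valid))

  # brute force on the real map
  sel <- co$masks[[id]]$data == 1L & sm$valid
  expect_equal(overlap_score(co$masks[[id]], sm)$score, mean(sm$stat[sel]))
  # sum variant
  expect_equal(overlap_score(co$masks[[id]], sm, statistic = "sum")$score,
               sum(sm$stat[sel]))

  # lesion entirely outside the valid region -> missing with warning
  nv <- sm
  nv$valid[] <- FALSE
  expect_warning(sc2 <- overlap_score(co$masks[[id]], nv), "missing")
  expect_true(is.na(sc2$score))
  expect_equal(sc2$n_voxels_used, 0)
})

test_that("survival dichotomizes strictly above the cutoff", {
  expect_equal(as.character(binarize_survival(c(366, 365, 364))),
               c("long", "short", "short"))
  expect_true(is.na(binarize_survival(NA)))
  expect_equal(levels(binarize_survival(100)), c("short", "long"))
})

test_that("roc_auc matches the all-pairs Mann-Whitney count with midrank ties", {
  r <- roc_auc(c(1, 2, 3, 4), factor(c("short", "short", "long", "long"),
                                     levels = c("short", "long")))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_auc(rep(2, 10), rep(c("a", "b"), 5))$auc, 0.5)

  set.seed(203)
  scores <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)  # many ties
  labels <- factor(sample(c("neg", "pos"), 50, replace = TRUE),
                   levels = c("neg", "pos"))
  r2 <- roc_auc(scores, labels)
  pos <- scores[labels == "pos"]; neg <- scores[labels == "neg"]
  u <- 0
  for (a in pos) for (b in neg)
    u <- u + (a > b) + 0.5 * (a == b)
  expect_equal(r2$auc, u / (length(pos) * length(neg)))

  # trapezoidal area of the returned curve equals the midrank AUC
  trap <- sum(diff(r2$fpr) * (head(r2$tpr, -1) + tail(r2$tpr, -1)) / 2)
  expect_equal(trap, r2$auc, tolerance = 1e-12)
  # curve runs (0,0) -> (1,1), nondecreasing
  expect_equal(c(r2$fpr[1], r2$tpr[1]), c(0, 0))
  expect_equal(c(tail(r2$fpr, 1), tail(r2$tpr, 1)), c(1, 1))
  expect_true(all(diff(r2$fpr) >= 0) && all(diff(r2$tpr) >= 0))
  expect_error(roc_auc(1:5, rep("pos", 5)), "2 levels|both classes")
})

test_that("roc_auc agrees with pROC and is antisymmetric under score negation", {
  set.seed(207)
  scores <- rnorm(80)
  labels <- factor(sample(c("neg", "pos"), 80, replace = TRUE),
                   levels = c("neg", "pos"))
  r <- roc_auc(scores, labels)
  expect_equal(r$auc + roc_auc(-scores, labels)$auc, 1.0)
  skip_if_not_installed("pROC")
  pr <- pROC::roc(labels, scores, levels = c("neg", "pos"),
                  direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("delong_compare: self-comparison, antisymmetry, pROC agreement", {
  set.seed(211)
  n <- 60
  labels <- factor(sample(c("neg", "pos"), n, replace = TRUE),
                   levels = c("neg", "pos"))
  a <- rnorm(n) + (labels == "pos")
  b <- 0.5 * a + rnorm(n)

  self <- delong_compare(a, a, labels)
  expect_equal(self$z, 0)
  expect_equal(self$p_two_sided, 1)

  d1 <- delong_compare(a, b, labels)
  d2 <- delong_compare(b, a, labels)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p_two_sided, d2$p_two_sided)

  skip_if_not_installed("pROC")
  ra <- pROC::roc(labels, a, levels = c("neg", "pos"), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(labels, b, levels = c("neg", "pos"), direction = "<",
                  quiet = TRUE)
  pt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(d1$z, unname(pt$statistic), tolerance = 1e-9)
  expect_equal(d1$p_two_sided, pt$p.value, tolerance = 1e-9)
})

test_that("DeLong variance is close to a paired-bootstrap variance (n = 20)", {
  set.seed(213)
  n <- 20
  labels <- factor(rep(c("neg", "pos"), each = 10), levels = c("neg", "pos"))
  a <- rnorm(n) + 1.2 * (labels == "pos")
  b <- rnorm(n) + 0.8 * (labels == "pos")
  d <- delong_compare(a, b, labels)

  auc_fast <- function(s, y) {
    r <- rank(s)
    n1 <- sum(y); n0 <- length(y) - n1
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  y <- labels == "pos"
  B <- 10000
  diffs <- numeric(B)
  kept <- 0
  for (bb in seq_len(B)) {
    ix <- sample(n, n, replace = TRUE)
    yy <- y[ix]
    if (sum(yy) == 0 || sum(yy) == n) next
    kept <- kept + 1
    diffs[kept] <- auc_fast(a[ix], yy) - auc_fast(b[ix], yy)
  }
  vboot <- var(diffs[seq_len(kept)])
  expect_lt(abs(d$var_diff - vboot) / vboot, 0.25)
})

test_that("DeLong is calibrated at the nominal level for fixed null scores", {
  set.seed(401)
  n <- 100
  B <- 200
  rej <- 0
  for (b in seq_len(B)) {
    labels <- factor(sample(rep(c("neg", "pos"), each = n / 2)),
                     levels = c("neg", "pos"))
    a <- rnorm(n)
    bscore <- 0.6 * a + rnorm(n)   # correlated scores, both independent of labels
    d <- delong_compare(a, bscore, labels)
    rej <- rej + (d$p_two_sided < 0.05)
  }
  expect_gte(rej / B, 0.02)
  expect_lte(rej / B, 0.09)
})

test_that("antisymmetric scores give mirrored AUCs and a lawful comparison", {
  labels <- factor(rep(c("neg", "pos"), each = 5), levels = c("neg", "pos"))
  a <- c(1:5, 6:10)   # perfect separation, auc_a = 1
  expect_equal(roc_auc(a, labels)$auc, 1)
  expect_equal(roc_auc(-a, labels)$auc, 0)
  # degenerate: both placements are constant -> zero variance, differing AUCs
  expect_error(delong_compare(a, -a, labels), "degenerate")
})

test_that("fit_score_model orders subjects by risk; perfect feature gives AUC 1", {
  labels <- factor(rep(c("short", "long"), each = 10),
                   levels = c("short", "long"))
  x <- c(rnorm(10, 0), rnorm(10, 10))
  # perfect separation legitimately saturates the fit
  sc <- suppressWarnings(fit_score_model(cbind(x = x), labels))
  expect_equal(roc_auc(sc, labels)$auc, 1.0)
  expect_error(fit_score_model(cbind(x = 1:3), factor(c("a", "a", "a"))),
               "binary")
})

test_that("null features give near-chance AUC (in-sample slightly optimistic)", {
  set.seed(217)
  n <- 500
  labels <- factor(sample(c("short", "long"), n, replace = TRUE),
                   levels = c("short", "long"))
  F <- cbind(a = rnorm(n), b = rnorm(n))
  auc_in <- roc_auc(fit_score_model(F, labels), labels)$auc
  expect_gte(auc_in, 0.5)
  expect_lte(auc_in, 0.6)
  # leave-one-out removes the optimism
  y01 <- as.integer(labels) - 1L
  Xd <- cbind(1, F)
  sc <- vapply(seq_len(n), function(i) {
    fit <- suppressWarnings(stats::glm.fit(Xd[-i, ], y01[-i],
                                           family = binomial()))
    sum(Xd[i, ] * fit$coefficients)
  }, numeric(1))
  auc_loo <- roc_auc(sc, labels)$auc
  expect_gte(auc_loo, 0.42)
  expect_lte(auc_loo, 0.58)
})

test_that("in-sample AUC of age+overlap is never below age alone", {
  for (s in c(301, 302, 303)) {
    sim <- generate_cohort(synth_params(n_subjects = 120, seed = s))
    rep <- survival_roc(sim$cohort, eval = "in_sample")
    expect_gte(rep$auc[["age+overlap"]] + 1e-9, rep$auc[["age"]])
  }
})

test_that("location-driven survival puts age+overlap ahead of age+volume", {
  sim <- generate_cohort(synth_params(n_subjects = 400, seed = 311))
  rep <- survival_roc(sim$cohort, eval = "in_sample")
  expect_gt(rep$auc[["age+overlap"]], rep$auc[["age+volume"]])
  expect_gt(rep$auc[["age+overlap"]], rep$auc[["age"]])
  d <- rep$delong[["age+overlap vs age+volume"]]
  expect_gt(d$z, 0)
})

test_that("loo evaluation of a null cohort removes the in-sample optimism", {
  # beta = 0 and baseline at the cutoff: classes are balanced and there is
  # nothing to learn; loo must not inherit the circular in-sample optimism
  # (it is, if anything, mildly pessimistic for near-chance classifiers)
  p <- synth_params(n_subjects = 150, seed = 321,
                    survival_beta_location = 0, survival_beta_age = 0,
                    survival_baseline_days = 365)
  sim <- generate_cohort(p)
  rep_loo <- survival_roc(sim$cohort, models = "age+overlap", eval = "loo")
  expect_lte(rep_loo$auc[["age+overlap"]], 0.62)
  expect_gte(rep_loo$auc[["age+overlap"]], 0.25)
})
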