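# Per-voxel t and z maps, critical values, FDR, thresholding.

test_that("coverage_mask keeps only voxels with variation on both sides", {
  # lesioned in all subjects -> no variation -> excluded even at min_count 1
  masks <- lapply(paste0("s", 1:4), make_mask, voxels = cbind(2, 2, 2))
  co <- assemble_cohort(masks, make_clinical(paste0("s", 1:4)))
  cm <- coverage_mask(co, min_count = 1)
  expect_false(cm[2, 2, 2])
  expect_false(any(cm))   # never-lesioned voxels excluded too

  # random cohort: equals the brute-force window test
  co2 <- random_cohort(30, seed = 51)
  cm2 <- coverage_mask(co2, min_count = 5)
  counts <- sum_map(co2)$counts
  expect_identical(cm2, counts >= 5 & counts <= 30 - 5)
})

test_that("per-voxel t equals the closed-form pooled two-sample t", {
  # y = (1,2,3,4), lesion indicator (0,0,1,1): means 1.5 vs 3.5, pooled sd
  # 0.7071 -> t = 2.828, df = 2
  masks <- list(make_mask("s1", voxels = cbind(1, 1, 1)),
                make_mask("s2", voxels = cbind(1, 1, 2)),
                make_mask("s3", voxels = cbind(2, 2, 2)),
                make_mask("s4", voxels = cbind(2, 2, 2)))
  clin <- make_clinical(paste0("s", 1:4), age = c(1, 2, 3, 4))
  co <- assemble_cohort(masks, clin)
  sm <- voxelwise_linear(co, "age_years", min_count = 1)
  expect_equal(sm$df, 2)
  expect_equal(sm$stat[2, 2, 2], 2.828427, tolerance = 1e-6)
  expect_equal(sm$p[2, 2, 2], 2 * pt(-2.828427, 2), tolerance = 1e-6)
})

test_that("constant attribute gives t = 0 at every valid voxel", {
  co <- random_cohort(12, seed = 55)
  co$clinical$age_years <- rep(47, 12)
  sm <- voxelwise_linear(co, "age_years", min_count = 2)
  expect_true(all(sm$stat[sm$valid] == 0))
})

test_that("t-map equals an independently coded per-voxel two-sample t everywhere", {
  sim <- generate_cohort(synth_params(n_subjects = 60, seed = 61,
                                      grid_shape = c(16, 16, 16),
                                      centre_means = list(idh_wildtype = c(7, 8, 8),
                                                          idh_mutant = c(9, 8, 8)),
                                      radius_lognorm = c(log(3), 0.35)))
  co <- sim$cohort
  sm <- voxelwise_linear(co, "age_years", min_count = 5)
  y <- co$clinical$age_years
  vox <- which(sm$valid)
  expect_gt(length(vox), 50)
  max_dt <- 0
  for (v in vox) {
    m <- vapply(co$masks, function(mk) mk$data[v], integer(1))
    tt <- t.test(y[m == 1], y[m == 0], var.equal = TRUE)
    max_dt <- max(max_dt, abs(unname(tt$statistic) - sm$stat[v]))
  }
  expect_lt(max_dt, 1e-8)
})

test_that("negating the attribute negates the t-map exactly", {
  co <- random_cohort(25, seed = 65)
  a <- voxelwise_linear(co, "age_years", min_count = 4)
  co$clinical$age_years <- -co$clinical$age_years
  b <- voxelwise_linear(co, "age_years", min_count = 4)
  expect_identical(a$valid, b$valid)
  expect_equal(a$stat[a$valid], -b$stat[b$valid])
})

test_that("per-voxel logistic Wald z matches the closed 2x2 form and glm", {
  # class x lesion table a=20,b=10,c=10,d=20 -> OR 4,
  # z = log(4)/sqrt(1/20+1/10+1/10+1/20)
  n <- 60
  lesion <- rep(c(1, 0), each = 30)
  cls <- c(rep("mutant", 20), rep("wildtype", 10),   # lesioned
           rep("mutant", 10), rep("wildtype", 20))   # non-lesioned
  ids <- sprintf("s%02d", 1:n)
  masks <- lapply(seq_len(n), function(i)
    make_mask(ids[i], voxels = if (lesion[i] == 1) cbind(2, 2, 2) else cbind(1, 1, 1)))
  clin <- make_clinical(ids, idh = cls)
  co <- assemble_cohort(masks, clin)
  zm <- voxelwise_logistic(co, "idh", min_count = 1)
  z_expected <- log(4) / sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)
  expect_equal(zm$stat[2, 2, 2], z_expected, tolerance = 1e-6)
  # independent oracle: glm Wald z at the same voxel
  g <- as.integer(factor(cls, levels = c("wildtype", "mutant"))) - 1L
  fit <- glm(g ~ lesion, family = binomial())
  expect_equal(zm$stat[2, 2, 2],
               unname(summary(fit)$coefficients["lesion", "z value"]),
               tolerance = 1e-6)

  # symmetric table -> z = 0
  cls2 <- c(rep("mutant", 15), rep("wildtype", 15),
            rep("mutant", 15), rep("wildtype", 15))
  co2 <- assemble_cohort(masks, make_clinical(ids, idh = cls2))
  zm2 <- voxelwise_logistic(co2, "idh", min_count = 1)
  expect_equal(zm2$stat[2, 2, 2], 0, tolerance = 1e-8)
})

test_that("logistic z-map agrees with glm on a random cohort and flags separation", {
  co <- random_cohort(40, shape = c(5, 5, 5), seed = 71)
  zm <- voxelwise_logistic(co, "idh", min_count = 3)
  g <- as.integer(co$clinical$idh) - 1L
  vox <- which(zm$valid)
  expect_gt(length(vox), 20)
  for (v in sample(vox, min(25, length(vox)))) {
    m <- vapply(co$masks, function(mk) mk$data[v], integer(1))
    fit <- suppressWarnings(glm(g ~ m, family = binomial()))
    expect_equal(zm$stat[v],
                 unname(summary(fit)$coefficients["m", "z value"]),
                 tolerance = 1e-5)
  }

  # plant a separated voxel: all lesioned subjects in class 1
  n <- 20
  ids <- sprintf("q%02d", 1:n)
  masks <- lapply(seq_len(n), function(i)
    make_mask(ids[i], voxels = if (i <= 8) cbind(3, 3, 3) else cbind(1, 1, 1)))
  cls <- c(rep("mutant", 8), rep("wildtype", 12))
  cs <- assemble_cohort(masks, make_clinical(ids, idh = cls))
  zs <- voxelwise_logistic(cs, "idh", min_count = 1)
  expect_false(zs$valid[3, 3, 3])
  expect_gte(zs$n_invalid_separation, 1)
})

test_that("swapping binary class labels negates the z-map", {
  co <- random_cohort(40, seed = 75)
  a <- voxelwise_logistic(co, "idh", min_count = 4)
  swapped <- factor(ifelse(co$clinical$idh == "wildtype", "mutant", "wildtype"),
                    levels = c("wildtype", "mutant"))
  co$clinical$idh <- swapped
  b <- voxelwise_logistic(co, "idh", min_count = 4)
  expect_identical(a$valid, b$valid)
  expect_equal(a$stat[a$valid], -b$stat[b$valid], tolerance = 1e-6)
})

test_that("critical_t reproduces two-sided critical values", {
  # 3.29 is the conventionally printed value; the exact t quantile is 3.2950,
  # within one unit of the last printed digit
  expect_equal(critical_t(0.001, 2162), 3.29, tolerance = 0.01 / 3.29)
  expect_equal(round(critical_t(0.05, 2162), 2), 1.96)
  expect_equal(critical_t(1, 100), 0)
  # definition: P(|T| >= t*) = alpha
  expect_equal(2 * pt(-critical_t(0.01, 7), 7), 0.01)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(0.037), 0.037)
  # monotone: sorted q nondecreasing in sorted p
  set.seed(81)
  p <- runif(200)^2
  q <- fdr_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p))
})

test_that("FDR thresholding equals the brute-force BH rejection set", {
  co <- random_cohort(50, shape = c(6, 6, 6), seed = 85)
  sm <- voxelwise_linear(co, "age_years", min_count = 5)
  alpha <- 0.3   # large alpha so the rejection set is non-trivial on noise
  thr <- threshold_map(sm, alpha, "fdr")
  # brute force BH step-up on the valid p-values
  p <- sm$p[sm$valid]
  m <- length(p)
  o <- order(p)
  k <- max(c(0, which(p[o] <= alpha * seq_len(m) / m)))
  rejected_vox <- which(sm$valid)[o[seq_len(k)]]
  got <- which(thr$mask)
  expect_setequal(got, rejected_vox)

  # uncorrected mode and degenerate alphas
  expect_identical(threshold_map(sm, 1, "uncorrected")$mask, sm$valid)
  expect_equal(sum(threshold_map(sm, 1e-300, "fdr")$mask), 0)
})

test_that("stat maps serialize as NIfTI pair plus JSON sidecar", {
  co <- random_cohort(20, seed = 91)
  sm <- voxelwise_linear(co, "age_years", min_count = 3)
  pre <- tempfile("tmap")
  write_stat_map(sm, pre)
  side <- jsonlite::read_json(paste0(pre, ".json"))
  expect_equal(side$kind, "t")
  expect_equal(side$df, 18)
  expect_equal(side$n_used, 20)
  back <- RNifti::readNifti(paste0(pre, "_stat.nii.gz"))
  expect_equal(array(as.numeric(back), dim = dim(back))[sm$valid],
               sm$stat[sm$valid], tolerance = 1e-6)
})
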