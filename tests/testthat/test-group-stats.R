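maps_from_matrix <- function(y, shape = NULL) {
  # y: subjects x voxels; each row becomes a 3D map
  if (is.null(shape)) shape <- c(ncol(y), 1, 1)
  lapply(seq_len(nrow(y)), function(s)
    volume3d(array(y[s, ], dim = shape), diag(4)))
}

test_that("one-sample t matches the textbook formula and its edge policies", {
  set.seed(25)
  n <- 20
  y <- matrix(rnorm(n * 50, mean = 0.3), n, 50)
  sm <- one_sample_t(maps_from_matrix(y), mu0 = 0)
  expect_equal(sm$df, 19)
  oracle <- apply(y, 2, function(v) (mean(v) - 0) / (sd(v) / sqrt(n)))
  expect_equal(as.vector(sm$data[, 1, 1]), oracle, tolerance = 1e-12)

  same <- matrix(2, 4, 10)
  sm2 <- one_sample_t(maps_from_matrix(same), mu0 = 2)
  expect_true(all(sm2$data == 0))
  expect_equal(sm2$qc$zero_variance_voxels, 10L)
  sm3 <- one_sample_t(maps_from_matrix(same), mu0 = 1)
  expect_true(all(sm3$data[, 1, 1] == restkit:::STAT_CAP))
  expect_error(one_sample_t(maps_from_matrix(same)[1]), "at least 2")
})

test_that("two-sample t without covariates equals the pooled-variance oracle", {
  set.seed(26)
  nA <- 12; nB <- 9; v <- 40
  yA <- matrix(rnorm(nA * v, 1), nA, v)
  yB <- matrix(rnorm(nB * v), nB, v)
  sm <- two_sample_t(maps_from_matrix(yA), maps_from_matrix(yB))
  expect_equal(sm$df, nA + nB - 2)
  pooled <- vapply(seq_len(v), function(j) {
    sp2 <- ((nA - 1) * var(yA[, j]) + (nB - 1) * var(yB[, j])) /
      (nA + nB - 2)
    (mean(yA[, j]) - mean(yB[, j])) / sqrt(sp2 * (1 / nA + 1 / nB))
  }, 1.0)
  expect_equal(as.vector(sm$data[, 1, 1]), pooled, tolerance = 1e-10)

  same <- maps_from_matrix(yA)
  expect_lt(max(abs(two_sample_t(same, same)$data)), 1e-10)
})

test_that("covariates orthogonal to the group contrast leave t unchanged", {
  set.seed(27)
  nA <- 10; nB <- 10; v <- 10
  n <- nA + nB
  y <- rbind(matrix(rnorm(nA * v, 0.5), nA, v), matrix(rnorm(nB * v), nB, v))
  indicator <- c(rep(1, nA), rep(0, nB))
  # orthogonalise against intercept, group AND the data columns, so the
  # group estimate and the residual sum of squares are both untouched
  ortho <- residuals(lm(rnorm(n) ~ cbind(indicator, y)))
  t0 <- two_sample_t(maps_from_matrix(y[1:nA, , drop = FALSE]),
                     maps_from_matrix(y[(nA + 1):n, , drop = FALSE]))
  t1 <- two_sample_t(maps_from_matrix(y[1:nA, , drop = FALSE]),
                     maps_from_matrix(y[(nA + 1):n, , drop = FALSE]),
                     covs = cbind(ortho))
  # identical RSS, one fewer residual df: t rescales by a known constant
  expect_equal(t1$data, t0$data * sqrt((n - 3) / (n - 2)), tolerance = 1e-8)
  expect_equal(t1$df, n - 3)
})

test_that("voxel-dependent image covariates enter the per-voxel design", {
  set.seed(28)
  nA <- 8; nB <- 8; v <- 12
  n <- nA + nB
  ic <- matrix(rnorm(n * v), n, v)               # e.g. gray-matter density
  y <- 0.8 * ic + matrix(rnorm(n * v, sd = 0.3), n, v)
  y[1:nA, ] <- y[1:nA, ] + 1
  A <- maps_from_matrix(y[1:nA, , drop = FALSE])
  B <- maps_from_matrix(y[(nA + 1):n, , drop = FALSE])
  icm <- maps_from_matrix(ic)
  sm <- two_sample_t(A, B, img_covs = icm)
  expect_equal(sm$df, n - 3)
  # oracle: per-voxel lm with the centred image covariate
  j <- 5
  g <- c(rep(1, nA), rep(0, nB))
  fit <- lm(y[, j] ~ g + scale(ic[, j], scale = FALSE))
  expect_equal(sm$data[j, 1, 1], summary(fit)$coefficients["g", "t value"],
               tolerance = 1e-8)
  # image covariate equal to the group indicator is rank deficient -> 0 + QC
  collinear <- maps_from_matrix(matrix(g, n, v))
  sm2 <- two_sample_t(A, B, img_covs = collinear)
  expect_true(all(sm2$data == 0))
  expect_equal(sm2$qc$degenerate_voxels, v)
})

test_that("paired t equals one-sample t of the differences", {
  set.seed(29)
  n <- 10; v <- 25
  yA <- matrix(rnorm(n * v), n, v)
  yB <- matrix(rnorm(n * v), n, v)
  A <- maps_from_matrix(yA); B <- maps_from_matrix(yB)
  pt <- paired_t(A, B)
  os <- one_sample_t(maps_from_matrix(yA - yB))
  expect_identical(pt$data, os$data)
  expect_equal(pt$df, n - 1)
  # textbook paired formula
  d <- yA - yB
  oracle <- apply(d, 2, function(x) mean(x) / (sd(x) / sqrt(n)))
  expect_equal(as.vector(pt$data[, 1, 1]), oracle, tolerance = 1e-10)
  # constant differences: capped, sign follows A - B
  Bshift <- maps_from_matrix(yA + 2)
  capped <- paired_t(A, Bshift)                  # differences = -2
  expect_true(all(capped$data == -restkit:::STAT_CAP))
  expect_error(paired_t(A, B[1:5]), "different lengths")
})

test_that("one-way ANOVA with 2 groups satisfies F = t^2", {
  set.seed(30)
  nA <- 9; nB <- 11; v <- 35
  yA <- matrix(rnorm(nA * v, 0.4), nA, v)
  yB <- matrix(rnorm(nB * v), nB, v)
  A <- maps_from_matrix(yA); B <- maps_from_matrix(yB)
  tmap <- two_sample_t(A, B)
  fmap <- one_way_anova(list(A, B))
  expect_equal(fmap$df, 1)
  expect_equal(fmap$df2, nA + nB - 2)
  expect_equal(fmap$data, tmap$data^2, tolerance = 1e-8)
})

test_that("ANOVA detects a planted 3-group mean shift where it was planted", {
  set.seed(31)
  v <- 64
  shape <- c(4, 4, 4)
  region <- logical(v); region[1:16] <- TRUE     # first z-slab
  mk_group <- function(n, shift) maps_from_matrix(
    matrix(rnorm(n * v), n, v) +
      outer(rep(shift, n), as.numeric(region)), shape = shape)
  g1 <- mk_group(8, 0); g2 <- mk_group(8, 0.8); g3 <- mk_group(8, 1.6)
  fmap <- one_way_anova(list(g1, g2, g3))
  expect_equal(c(fmap$df, fmap$df2), c(2, 21))
  fin <- fmap$data[as.logical(array(region, shape))]
  fout <- fmap$data[!as.logical(array(region, shape))]
  expect_gt(median(fin), median(fout))
})

test_that("null p-values are uniform under exchangeable groups", {
  set.seed(32)
  v <- 500; n <- 16
  y <- matrix(rnorm(n * v), n, v)
  g1 <- maps_from_matrix(y[1:8, ]); g2 <- maps_from_matrix(y[9:16, ])
  fmap <- one_way_anova(list(g1, g2))
  p <- as.vector(stat_to_p(fmap)$data[, 1, 1])
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("correlation map: self-regressor, reduction, partial oracle", {
  set.seed(33)
  n <- 15; v <- 20
  y <- matrix(rnorm(n * v), n, v)
  maps <- maps_from_matrix(y)
  cm <- correlation_map(maps, y[, 7])
  expect_equal(cm$data[7, 1, 1], 1, tolerance = 1e-12)
  expect_equal(cm$df, n - 2)
  oracle <- apply(y, 2, function(col) cor(col, y[, 7]))
  expect_equal(as.vector(cm$data[, 1, 1]), oracle, tolerance = 1e-10)

  iq <- rnorm(n); age <- rnorm(n)
  cm2 <- correlation_map(maps, iq, covs = cbind(age))
  expect_equal(cm2$df, n - 3)
  oracle2 <- apply(y, 2, function(col) partial_r(col, iq, cbind(age)))
  expect_equal(as.vector(cm2$data[, 1, 1]), oracle2, tolerance = 1e-10)

  expect_error(correlation_map(maps, rep(1, n)), "constant")
})
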