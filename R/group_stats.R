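#' @title Voxel-wise group statistics
#' @description One-sample, two-sample and paired t-tests, one-way
#'   ANOVA/ANCOVA, and across-subject correlation, each producing a
#'   `StatMap`: a `Volume3D` carrying the statistic type, its degrees of
#'   freedom and QC counters. Designs may include per-subject text
#'   covariates and voxel-dependent image covariates (one 3D map per
#'   subject, mean-centred per voxel before entering the design).
#' @name group-stats
NULL

stat_map <- function(data, affine, statistic, df, df2 = NULL, qc = list()) {
  structure(list(data = data, affine = affine, statistic = statistic,
                 df = df, df2 = df2, qc = qc),
            class = c("StatMap", "Volume3D"))
}

#' @export
print.StatMap <- function(x, ...) {
  d <- dim(x$data)
  dfs <- if (is.null(x$df2)) sprintf("df=%g", x$df)
         else sprintf("df=(%g, %g)", x$df, x$df2)
  cat(sprintf("<StatMap [%s] %dx%dx%d, %s>\n", x$statistic,
              d[1], d[2], d[3], dfs))
  invisible(x)
}

# cap applied where a zero-variance voxel would give an infinite statistic
STAT_CAP <- 1e6

# subjects x V matrix of in-mask values from a list of 3D maps
stack_maps <- function(maps, mask) {
  stopifnot(length(maps) >= 1L)
  ref <- maps[[1]]
  shape <- spatial_dim(ref)
  for (m in maps) {
    if (!all(spatial_dim(m) == shape))
      stop("group maps are not on a common grid")
    if (max(abs(m$affine - ref$affine)) > 1e-6)
      stop("group maps do not share an affine")
  }
  sel <- as.vector(mask$data)
  do.call(rbind, lapply(maps, function(m) as.vector(m$data)[sel]))
}

fill_map <- function(values, mask, shape) {
  out <- array(0, dim = shape)
  out[mask$data] <- values
  out
}

#' One-sample t-test across subjects
#'
#' Per in-mask voxel, t = (mean - mu0) / (sd / sqrt(n)) with df = n - 1.
#' Zero-variance voxels give 0 when the mean equals `mu0`, otherwise a
#' sign-preserving capped value; both are QC-counted.
#'
#' @param maps list of `Volume3D` maps, one per subject (n >= 2).
#' @param mu0 null value (e.g. 1 for standardized ReHo/ALFF maps).
#' @param mask optional `Mask`.
#' @return a `StatMap` (`t`, df = n - 1).
#' @export
one_sample_t <- function(maps, mu0 = 0, mask = NULL) {
  n <- length(maps)
  if (n < 2L) stop("one_sample_t: need at least 2 subjects")
  mask <- check_mask(mask, maps[[1]])
  y <- stack_maps(maps, mask)
  mu <- colMeans(y)
  sdv <- apply(y, 2L, stats::sd)
  t <- numeric(ncol(y))
  ok <- sdv > 0
  t[ok] <- (mu[ok] - mu0) / (sdv[ok] / sqrt(n))
  t[!ok] <- sign(mu[!ok] - mu0) * STAT_CAP
  t <- pmin(pmax(t, -STAT_CAP), STAT_CAP)        # degenerate variance policy
  stat_map(fill_map(t, mask, spatial_dim(maps[[1]])), maps[[1]]$affine,
           "t", df = n - 1,
           qc = list(zero_variance_voxels = sum(!ok),
                     capped_voxels = sum(abs(t) >= STAT_CAP)))
}

check_image_covariates <- function(img_covs, n, mask) {
  if (is.null(img_covs)) return(NULL)
  if (length(img_covs) != n)
    stop("need one image covariate per subject (", n, "), got ",
         length(img_covs))
  ic <- stack_maps(img_covs, mask)               # n x V
  sweep(ic, 2L, colMeans(ic))                    # mean-centred per voxel
}

# GLM t for the first design column, shared design X (no image covariates)
glm_t_shared <- function(y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("group design is rank deficient")
  n <- nrow(X)
  df <- n - qrX$rank
  XtXinv <- solve(crossprod(X))
  beta <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  s2 <- colSums(res^2) / df
  se <- sqrt(XtXinv[1, 1] * s2)
  t <- numeric(ncol(y))
  ok <- se > 0
  t[ok] <- beta[1, ok] / se[ok]
  t[!ok] <- sign(beta[1, !ok]) * STAT_CAP
  t <- pmin(pmax(t, -STAT_CAP), STAT_CAP)
  list(t = t, df = df, n_degenerate = sum(!ok))
}

# per-voxel GLM t for column 1 of [base | image covariate]
glm_t_pervoxel <- function(y, base, ic) {
  n <- nrow(y)
  t <- numeric(ncol(y))
  df_out <- n - (ncol(base) + 1L)
  n_bad <- 0L
  for (v in seq_len(ncol(y))) {
    X <- cbind(base, ic[, v])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) { n_bad <- n_bad + 1L; next }
    df <- n - qrX$rank
    beta <- qr.coef(qrX, y[, v])
    res <- qr.resid(qrX, y[, v])
    se <- sqrt(solve(crossprod(X))[1, 1] * sum(res^2) / df)
    t[v] <- if (se > 0) beta[1] / se else sign(beta[1]) * STAT_CAP
    if (se == 0) n_bad <- n_bad + 1L
  }
  t <- pmin(pmax(t, -STAT_CAP), STAT_CAP)
  list(t = t, df = df_out, n_degenerate = n_bad)
}

#' Two-sample t-test with optional covariates
#'
#' Equal-variance GLM: per voxel, the map values are regressed on a group
#' indicator, an intercept, optional per-subject text covariates
#' (concatenated group A then group B) and an optional voxel-dependent image
#' covariate; t is the group contrast (A - B) over its standard error,
#' df = n - rank. Without covariates this is the classical pooled-variance
#' two-sample t.
#'
#' @param groupA,groupB lists of `Volume3D` maps (each n >= 2).
#' @param covs optional (nA+nB) x q covariate matrix.
#' @param img_covs optional list of nA+nB `Volume3D` image covariates.
#' @param mask optional `Mask`.
#' @return a `StatMap` (`t`).
#' @export
two_sample_t <- function(groupA, groupB, covs = NULL, img_covs = NULL,
                         mask = NULL) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L) stop("two_sample_t: each group needs >= 2 subjects")
  n <- nA + nB
  mask <- check_mask(mask, groupA[[1]])
  y <- stack_maps(c(groupA, groupB), mask)
  covs <- check_covariates(covs, n)
  indicator <- c(rep(1, nA), rep(0, nB))
  base <- cbind(group = indicator, intercept = rep(1, n), covs)
  ic <- check_image_covariates(img_covs, n, mask)
  fit <- if (is.null(ic)) glm_t_shared(y, base)
         else glm_t_pervoxel(y, base, ic)
  stat_map(fill_map(fit$t, mask, spatial_dim(groupA[[1]])),
           groupA[[1]]$affine, "t", df = fit$df,
           qc = list(degenerate_voxels = fit$n_degenerate))
}

#' Paired t-test
#'
#' One-sample t-test of the per-subject differences A - B against 0.
#' Constant nonzero differences would give an infinite t and are capped
#' (sign-preserving); see [one_sample_t()].
#'
#' @param groupA,groupB equal-length lists of `Volume3D` maps, subject order
#'   aligned.
#' @param mask optional `Mask`.
#' @return a `StatMap` (`t`, df = n - 1).
#' @export
paired_t <- function(groupA, groupB, mask = NULL) {
  if (length(groupA) != length(groupB))
    stop("paired_t: groups have different lengths (",
         length(groupA), " vs ", length(groupB), ")")
  diffs <- mapply(function(a, b) volume3d(a$data - b$data, a$affine),
                  groupA, groupB, SIMPLIFY = FALSE)
  one_sample_t(diffs, mu0 = 0, mask = mask)
}

#' One-way ANOVA / ANCOVA across groups
#'
#' Per voxel, F compares the full model (group dummies + intercept +
#' covariates + optional image covariate) against the reduced model without
#' the group dummies; (df1, df2) = (G - 1, N - rank_full). Rank-deficient or
#' zero-residual voxels give 0 and are QC-counted.
#'
#' @param groups list of >= 2 lists of `Volume3D` maps, each with >= 2
#'   subjects.
#' @param covs optional N x q covariate matrix (subjects concatenated in
#'   group order).
#' @param img_covs optional list of N image covariates.
#' @param mask optional `Mask`.
#' @return a `StatMap` (`F`, df = (G-1, N-rank)).
#' @export
one_way_anova <- function(groups, covs = NULL, img_covs = NULL, mask = NULL) {
  g <- length(groups)
  if (g < 2L) stop("one_way_anova: need at least 2 groups")
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2L)) stop("one_way_anova: every group needs >= 2 subjects")
  n <- sum(sizes)
  maps <- do.call(c, groups)
  mask <- check_mask(mask, maps[[1]])
  y <- stack_maps(maps, mask)
  covs <- check_covariates(covs, n)
  grp <- factor(rep(seq_len(g), sizes))
  dummies <- stats::model.matrix(~grp)[, -1, drop = FALSE]
  reduced <- cbind(intercept = rep(1, n), covs)
  full <- cbind(reduced, dummies)
  ic <- check_image_covariates(img_covs, n, mask)
  fvals <- numeric(ncol(y))
  n_bad <- 0L
  if (is.null(ic)) {
    qf <- qr(full); qr_ <- qr(reduced)
    if (qf$rank < ncol(full)) stop("one_way_anova: design is rank deficient")
    df1 <- qf$rank - qr_$rank
    df2 <- n - qf$rank
    rss_f <- colSums(qr.resid(qf, y)^2)
    rss_r <- colSums(qr.resid(qr_, y)^2)
    ok <- rss_f > 0
    fvals[ok] <- ((rss_r[ok] - rss_f[ok]) / df1) / (rss_f[ok] / df2)
    fvals[!ok & rss_r > 0] <- STAT_CAP
    n_bad <- sum(!ok)
  } else {
    df1 <- g - 1L
    df2 <- n - (ncol(full) + 1L)
    for (v in seq_len(ncol(y))) {
      Xf <- cbind(full, ic[, v]); Xr <- cbind(reduced, ic[, v])
      qf <- qr(Xf); qr_ <- qr(Xr)
      if (qf$rank < ncol(Xf)) { n_bad <- n_bad + 1L; next }
      rss_f <- sum(qr.resid(qf, y[, v])^2)
      rss_r <- sum(qr.resid(qr_, y[, v])^2)
      if (rss_f <= 0) { n_bad <- n_bad + 1L; next }
      fvals[v] <- ((rss_r - rss_f) / (qf$rank - qr_$rank)) /
        (rss_f / (n - qf$rank))
    }
  }
  fvals[fvals < 0] <- 0
  fvals <- pmin(fvals, STAT_CAP)
  stat_map(fill_map(fvals, mask, spatial_dim(maps[[1]])), maps[[1]]$affine,
           "F", df = df1, df2 = df2,
           qc = list(degenerate_voxels = n_bad))
}

#' Across-subject correlation map
#'
#' Per in-mask voxel, the Pearson correlation across subjects between the
#' map values and a per-subject regressor (e.g. an IQ column); partial
#' correlation when covariates are given. df = n - 2 - q.
#'
#' @param maps list of `Volume3D` maps, one per subject (n >= 3).
#' @param regressor numeric vector, one value per subject.
#' @param covs optional n x q covariate matrix (partial correlation).
#' @param mask optional `Mask`.
#' @return a `StatMap` (`r`, df = n - 2 - q).
#' @export
correlation_map <- function(maps, regressor, covs = NULL, mask = NULL) {
  n <- length(maps)
  if (n < 3L) stop("correlation_map: need at least 3 subjects")
  regressor <- as.numeric(regressor)
  if (length(regressor) != n)
    stop("correlation_map: regressor length != number of subjects")
  if (stats::sd(regressor) == 0)
    stop("correlation_map: regressor is constant")
  mask <- check_mask(mask, maps[[1]])
  y <- stack_maps(maps, mask)
  covs <- check_covariates(covs, n)
  q <- if (is.null(covs)) 0L else ncol(covs)
  if (!is.null(covs)) {
    qrX <- design_qr(covs, n)
    regressor <- qr.resid(qrX, regressor)
    y <- qr.resid(qrX, y)
  }
  xc <- regressor - mean(regressor)
  yc <- sweep(y, 2L, colMeans(y))
  xss <- sum(xc^2)
  yss <- colSums(yc^2)
  r <- numeric(ncol(y))
  ok <- yss > 0
  r[ok] <- drop(crossprod(xc, yc[, ok, drop = FALSE])) / sqrt(xss * yss[ok])
  r <- pmin(1, pmax(-1, r))
  stat_map(fill_map(r, mask, spatial_dim(maps[[1]])), maps[[1]]$affine,
           "r", df = n - 2L - q,
           qc = list(zero_variance_voxels = sum(!ok)))
}
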