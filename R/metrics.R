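#' @title Resting-state metric maps
#' @description A `MetricMap` is a `Volume3D` tagged with the metric it
#'   carries (`fc_r`, `fc_z`, `reho`, `alff`, `falff`), the parameters used,
#'   and QC counters (voxels where a degenerate series forced a 0 instead of
#'   NaN).
#' @name metric-maps
NULL

metric_map <- function(data, affine, metric, params = list(), qc = list()) {
  structure(list(data = data, affine = affine, metric = metric,
                 params = params, qc = qc),
            class = c("MetricMap", "Volume3D"))
}

#' @export
print.MetricMap <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<MetricMap [%s] %dx%dx%d>\n", x$metric, d[1], d[2], d[3]))
  invisible(x)
}

#' Pearson correlation between two time courses
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("pearson_r: unequal lengths")
  if (length(x) < 3L) stop("pearson_r: need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_r: zero-variance input; correlation undefined")
  stats::cor(x, y)
}

#' Partial correlation given nuisance covariates
#'
#' The correlation of the two series after each is replaced by its OLS
#' residual on an intercept plus the covariate columns. With no covariates
#' this reduces to [pearson_r()].
#'
#' @param x,y numeric vectors of equal length.
#' @param covs T x p covariate matrix or `NULL`.
#' @return partial correlation coefficient.
#' @export
partial_r <- function(x, y, covs = NULL) {
  covs <- check_covariates(covs, length(x))
  if (is.null(covs)) return(pearson_r(x, y))
  qrX <- design_qr(covs, length(x))
  pearson_r(qr.resid(qrX, as.numeric(x)), qr.resid(qrX, as.numeric(y)))
}

#' Seed-based functional connectivity map
#'
#' Correlates a reference (seed) time course with every in-mask voxel's
#' series: Pearson correlation, or partial correlation when nuisance
#' covariates are supplied. Voxels with a constant series get r = 0 and are
#' tallied in the QC counter, so written maps never contain NaN.
#'
#' @param vol a `Volume4D`.
#' @param seed numeric vector of length T (e.g. from
#'   [extract_roi_timecourse()]).
#' @param mask optional `Mask`.
#' @param covs optional T x p covariate matrix (partial correlation).
#' @param fisher_z also compute the Fisher z map, `z = atanh(r)` with `|r|`
#'   clipped to 1 - 1e-7 (clipped voxels are QC-counted).
#' @return list with `r` (a `MetricMap`) and `z` (`MetricMap` or `NULL`).
#' @export
seed_fc_map <- function(vol, seed, mask = NULL, covs = NULL,
                        fisher_z = FALSE) {
  mask <- check_mask(mask, vol)
  tt <- n_timepoints(vol)
  seed <- as.numeric(seed)
  if (length(seed) != tt)
    stop("seed_fc_map: seed length ", length(seed), " != T = ", tt)
  covs <- check_covariates(covs, tt)
  mat <- timeseries_matrix(vol, mask)
  if (!is.null(covs)) {
    qrX <- design_qr(covs, tt)
    seed <- qr.resid(qrX, seed)
    mat <- qr.resid(qrX, mat)
  }
  sc <- seed - mean(seed)
  mc <- sweep(mat, 2L, colMeans(mat))
  seed_ss <- sum(sc^2)
  vox_ss <- colSums(mc^2)
  if (seed_ss == 0) stop("seed_fc_map: seed series is constant")
  r <- numeric(ncol(mat))
  ok <- vox_ss > 0
  r[ok] <- drop(crossprod(sc, mc[, ok, drop = FALSE])) /
    sqrt(seed_ss * vox_ss[ok])
  r <- pmin(1, pmax(-1, r))
  shape <- spatial_dim(vol)
  rmap <- array(0, dim = shape)
  rmap[mask$data] <- r
  params <- list(partial = !is.null(covs))
  qc <- list(constant_voxels = sum(!ok))
  out <- list(
    r = metric_map(rmap, vol$affine, "fc_r", params, qc),
    z = NULL)
  if (fisher_z) {
    clip <- 1 - 1e-7
    clipped <- sum(abs(r) > clip)
    zmap <- array(0, dim = shape)
    zmap[mask$data] <- atanh(pmin(clip, pmax(-clip, r)))
    out$z <- metric_map(zmap, vol$affine, "fc_z", params,
                        c(qc, list(clipped_voxels = clipped)))
  }
  out
}

#' Pairwise ROI-to-ROI correlation matrix
#'
#' @param tcs list of >= 2 equal-length time courses (one per ROI).
#' @param covs optional covariates: partial correlations are computed.
#' @return symmetric matrix of correlations with unit diagonal.
#' @export
roi_wise_fc <- function(tcs, covs = NULL) {
  if (length(tcs) < 2L) stop("roi_wise_fc: need at least 2 ROIs")
  tt <- length(tcs[[1]])
  if (!all(vapply(tcs, length, 1L) == tt))
    stop("roi_wise_fc: ROI time courses have unequal lengths")
  k <- length(tcs)
  out <- diag(1, k)
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      out[i, j] <- out[j, i] <- partial_r(tcs[[i]], tcs[[j]], covs)
  if (!is.null(names(tcs))) dimnames(out) <- list(names(tcs), names(tcs))
  out
}

#' Kendall's coefficient of concordance (KCC)
#'
#' For K time courses over n time points, each series is ranked across time
#' (average ranks on ties, no tie correction in the denominator); with rank
#' sums R_i per time point and mean rank sum Rbar = K(n+1)/2,
#' W = (sum R_i^2 - n Rbar^2) / ((1/12) K^2 (n^3 - n)), in \[0, 1\].
#'
#' @param cluster numeric matrix, n time points x K time courses.
#' @return W in \[0, 1\].
#' @export
kcc <- function(cluster) {
  cluster <- as.matrix(cluster)
  n <- nrow(cluster); k <- ncol(cluster)
  if (k < 2L) stop("kcc: need at least 2 time courses")
  if (n < 2L) stop("kcc: need at least 2 time points")
  ranks <- apply(cluster, 2L, rank)             # average ranks on ties
  ri <- rowSums(ranks)
  rbar <- k * (n + 1) / 2
  (sum(ri^2) - n * rbar^2) / (k^2 * (n^3 - n) / 12)
}

# neighbourhood stencils: offsets excluding the centre voxel
stencil_offsets <- function(neighbors) {
  if (!neighbors %in% c(6L, 18L, 26L))
    stop("neighbors must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(neighbors),
                 "6"  = ord == 1L,
                 "18" = ord >= 1L & ord <= 2L,
                 "26" = ord >= 1L)
  g[keep, , drop = FALSE]
}

# shift a 3D or 4D array by an integer spatial offset, zero-filling
shift_spatial <- function(arr, off) {
  d <- dim(arr)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    if (off[a] >= 0) {
      src[[a]] <- seq_len(d[a] - off[a])
      dst[[a]] <- src[[a]] + off[a]
    } else {
      src[[a]] <- (1 - off[a]):d[a]
      dst[[a]] <- src[[a]] + off[a]
    }
    if (length(src[[a]]) == 0L) return(out)
  }
  if (length(d) == 4L)
    out[dst[[1]], dst[[2]], dst[[3]], ] <- arr[src[[1]], src[[2]], src[[3]], ]
  else
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Regional homogeneity (ReHo) map
#'
#' Kendall's W of each in-mask voxel's series with those of its nearest
#' neighbours (6 faces, 18 faces+edges, or 26 all), i.e. cluster sizes
#' K = 7, 19 or 27 when the full neighbourhood is present. Neighbours
#' outside the mask or the grid are dropped and K reduced accordingly;
#' voxels left with fewer than 2 series get 0. The per-voxel effective K is
#' returned alongside the map.
#'
#' @param vol a `Volume4D` with T >= 4.
#' @param mask optional `Mask`.
#' @param neighbors 6, 18 or 26.
#' @return a `MetricMap` (`reho`); `$params$effective_k` holds the K map.
#' @export
reho_map <- function(vol, mask = NULL, neighbors = 26L) {
  mask <- check_mask(mask, vol)
  tt <- n_timepoints(vol)
  if (tt < 4L) stop("reho_map: need T >= 4")
  shape <- spatial_dim(vol)
  # per-voxel temporal ranks, zeroed outside the mask
  mat <- timeseries_matrix(vol, mask)           # T x V
  rk <- apply(mat, 2L, rank)
  rank_arr <- array(0, dim = c(shape, tt))
  idx <- which(mask$data)
  flat <- matrix(rank_arr, prod(shape), tt)
  flat[idx, ] <- t(rk)
  rank_arr <- array(flat, dim = c(shape, tt))
  inmask <- array(as.double(mask$data), dim = shape)

  sum_r <- rank_arr                              # centre voxel contribution
  kmap <- inmask
  for (o in seq_len(nrow(stencil <- stencil_offsets(neighbors)))) {
    off <- stencil[o, ]
    sum_r <- sum_r + shift_spatial(rank_arr, off)
    kmap <- kmap + shift_spatial(inmask, off)
  }
  n <- tt
  sum_sq <- array(rowSums(matrix(sum_r^2, prod(shape), tt)), dim = shape)
  rbar <- kmap * (n + 1) / 2
  denom <- kmap^2 * (n^3 - n) / 12
  w <- array(0, dim = shape)
  usable <- mask$data & kmap >= 2
  w[usable] <- (sum_sq[usable] - n * rbar[usable]^2) / denom[usable]
  w[w < 0] <- 0
  kmap[!mask$data] <- 0
  metric_map(w, vol$affine, "reho",
             params = list(neighbors = neighbors, effective_k = kmap),
             qc = list(underpopulated_voxels = sum(mask$data & kmap < 2)))
}

# per-voxel one-sided amplitude spectrum of a T x V matrix
amplitude_spectrum <- function(mat, tr) {
  n <- nrow(mat)
  npad <- good_fft_length(n)
  centred <- sweep(mat, 2L, colMeans(mat))
  padded <- rbind(centred, matrix(0, npad - n, ncol(mat)))
  ft <- stats::mvfft(padded)
  half <- seq_len(floor(npad / 2)) + 1L          # bins k = 1 .. npad/2
  amp <- Mod(ft[half, , drop = FALSE]) / sqrt(npad)
  list(freqs = (half - 1L) / (npad * tr), amp = amp, npad = npad)
}

#' Amplitude of low-frequency fluctuation (ALFF) map
#'
#' Per in-mask voxel: the series (mean removed) is zero-padded to the
#' shortest 5-smooth FFT length, transformed, and the square root of the
#' power spectrum density averaged over the DFT bins inside the band
#' (closed interval, DC excluded). The absolute scale is arbitrary up to a
#' constant; standardized maps ([standardize_by_mask_mean()]) and fALFF are
#' the stable quantities.
#'
#' @param vol a `Volume4D`.
#' @param low,high band edges in Hz (typically 0.01-0.08); `high` must not
#'   exceed the Nyquist frequency.
#' @param mask optional `Mask`.
#' @return a `MetricMap` (`alff`), non-negative.
#' @export
alff_map <- function(vol, low = 0.01, high = 0.08, mask = NULL) {
  check_band(low, high)
  mask <- check_mask(mask, vol)
  nyq <- 1 / (2 * vol$tr)
  if (high > nyq + 1e-12)
    stop("alff_map: band.high = ", high, " Hz exceeds Nyquist = ", nyq, " Hz")
  mat <- timeseries_matrix(vol, mask)
  sp <- amplitude_spectrum(mat, vol$tr)
  inband <- sp$freqs >= low - 1e-12 & sp$freqs <= high + 1e-12
  if (!any(inband))
    stop("alff_map: no DFT bin falls inside [", low, ", ", high,
         "] Hz; frequency resolution is ", signif(1 / (sp$npad * vol$tr), 3),
         " Hz")
  alff <- colMeans(sp$amp[inband, , drop = FALSE])
  out <- array(0, dim = spatial_dim(vol))
  out[mask$data] <- alff
  metric_map(out, vol$affine, "alff",
             params = list(band = c(low, high), npad = sp$npad))
}

#' Fractional ALFF (fALFF) map
#'
#' Ratio of the summed amplitude inside the low-frequency band to the
#' summed amplitude over the entire range (0, Nyquist]; the DC bin is
#' excluded from both. Input must *not* be bandpass filtered. Constant
#' series give 0 and are QC-counted.
#'
#' @inheritParams alff_map
#' @return a `MetricMap` (`falff`) with values in \[0, 1\].
#' @export
falff_map <- function(vol, low = 0.01, high = 0.08, mask = NULL) {
  check_band(low, high)
  mask <- check_mask(mask, vol)
  mat <- timeseries_matrix(vol, mask)
  sp <- amplitude_spectrum(mat, vol$tr)
  nyq <- 1 / (2 * vol$tr)
  inband <- sp$freqs >= low - 1e-12 & sp$freqs <= min(high, nyq) + 1e-12
  if (!any(inband))
    stop("falff_map: no DFT bin falls inside the band")
  num <- colSums(sp$amp[inband, , drop = FALSE])
  den <- colSums(sp$amp)
  f <- ifelse(den > 0, num / den, 0)
  out <- array(0, dim = spatial_dim(vol))
  out[mask$data] <- f
  metric_map(out, vol$affine, "falff",
             params = list(band = c(low, high), npad = sp$npad),
             qc = list(zero_amplitude_voxels = sum(den == 0)))
}

#' Divide a map by its in-mask mean
#'
#' The standardization used for ReHo and ALFF maps before group analysis:
#' each in-mask voxel is divided by the mean in-mask value, so the
#' standardized in-mask mean is exactly 1. Out-of-mask voxels are zeroed.
#'
#' @param map a `Volume3D` or `MetricMap`.
#' @param mask a nonempty `Mask`.
#' @return object of the same class as `map`.
#' @export
standardize_by_mask_mean <- function(map, mask) {
  mask <- check_mask(mask, map)
  mu <- mean(map$data[mask$data])
  if (!is.finite(mu) || mu == 0)
    stop("standardize_by_mask_mean: in-mask mean is zero")
  out <- map
  out$data <- array(0, dim = dim(map$data))
  out$data[mask$data] <- map$data[mask$data] / mu
  if (inherits(out, "MetricMap"))
    out$params <- c(out$params, list(standardized = TRUE))
  out
}

#' One-sided power spectrum of a time course
#'
#' Periodogram on the zero-padded (5-smooth) length, with an option to
#' remove the linear trend first. The mean is always removed. Powers at
#' interior bins are doubled so that the total equals the centred sum of
#' squares (Parseval).
#'
#' @param x numeric vector, length >= 4.
#' @param tr sampling interval in seconds.
#' @param detrend_first remove the least-squares line before transforming.
#' @return data.frame with columns `frequency` (Hz, 0 to Nyquist) and
#'   `power`.
#' @export
power_spectrum <- function(x, tr, detrend_first = FALSE) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("power_spectrum: need at least 4 points")
  if (detrend_first) x <- detrend(x)
  n <- length(x)
  npad <- good_fft_length(n)
  xc <- x - mean(x)
  padded <- c(xc, numeric(npad - n))
  ft <- stats::fft(padded)
  nhalf <- floor(npad / 2)
  k <- 0:nhalf
  p <- Mod(ft[k + 1L])^2 / npad
  mult <- rep(2, length(k))
  mult[1] <- 1
  if (npad %% 2 == 0) mult[length(k)] <- 1       # Nyquist bin not mirrored
  data.frame(frequency = k / (npad * tr), power = p * mult)
}
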