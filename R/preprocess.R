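#' Remove the linear trend from a time course or volume
#'
#' Fits a straight line to each time course by least squares, subtracts it,
#' and adds the original mean back, so slow scanner drift is removed while
#' the baseline signal level is kept.
#'
#' @param x numeric vector (one time course) or `Volume4D`.
#' @param mask optional `Mask` when `x` is a volume; out-of-mask voxels pass
#'   through unchanged.
#' @return object of the same type as `x`.
#' @export
detrend <- function(x, mask = NULL) UseMethod("detrend")

#' @export
detrend.default <- function(x, mask = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("detrend: need at least 3 time points")
  t0 <- seq_len(n) - (n + 1) / 2              # centred time, orthogonal to 1
  slope <- sum(t0 * x) / sum(t0 * t0)
  x - slope * t0
}

#' @export
detrend.Volume4D <- function(x, mask = NULL) {
  mask <- check_mask(mask, x)
  tt <- n_timepoints(x)
  mat <- timeseries_matrix(x, mask)            # T x V
  t0 <- seq_len(tt) - (tt + 1) / 2
  slope <- drop(crossprod(t0, mat)) / sum(t0 * t0)
  res <- mat - outer(t0, slope)
  put_timeseries(x, mask, res)
}

# T x V matrix of in-mask voxel series
timeseries_matrix <- function(vol, mask) {
  d <- dim(vol$data)
  m2 <- matrix(vol$data, prod(d[1:3]), d[4])
  t(m2[as.vector(mask$data), , drop = FALSE])
}

# write a T x V matrix back into a copy of vol at the in-mask voxels
put_timeseries <- function(vol, mask, mat) {
  d <- dim(vol$data)
  m2 <- matrix(vol$data, prod(d[1:3]), d[4])
  m2[as.vector(mask$data), ] <- t(mat)
  volume4d(array(m2, dim = d), vol$affine, vol$tr)
}

#' Smallest 5-smooth FFT length at least n
#'
#' Zero-padding target for the ideal filter and the spectrum utilities: the
#' smallest integer >= n whose prime factors are all in {2, 3, 5}, the
#' "shortest FFT length" convention of AFNI's spectrum tools.
#'
#' @param n positive integer.
#' @return integer >= n.
#' @export
good_fft_length <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("good_fft_length: n must be >= 1")
  is_smooth <- function(m) {
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    m == 1L
  }
  m <- n
  while (!is_smooth(m)) m <- m + 1L
  m
}

#' Ideal rectangle-window bandpass filter
#'
#' Transforms each time course to the frequency domain (zero-padded to the
#' shortest 5-smooth length), zeroes every DFT bin whose frequency falls
#' outside the closed interval `[low, high]`, and transforms back. A least
#' squares line is removed before the transform and added back afterwards
#' ("retrend"), so the mean and linear trend survive filtering. `low = 0`
#' gives a pure low-pass; `high` above the Nyquist frequency `1/(2 tr)`
#' gives a pure high-pass.
#'
#' @param x numeric vector or `Volume4D`.
#' @param low,high band edges in Hz, `0 <= low < high`.
#' @param tr sampling interval in seconds (taken from the volume when `x`
#'   is a `Volume4D`).
#' @param mask optional `Mask` for the volume method.
#' @return filtered object of the same type as `x`.
#' @export
ideal_bandpass <- function(x, low, high, tr = NULL, mask = NULL)
  UseMethod("ideal_bandpass")

#' @export
ideal_bandpass.default <- function(x, low, high, tr = NULL, mask = NULL) {
  if (is.null(tr)) stop("ideal_bandpass: tr is required for a plain vector")
  x <- as.numeric(x)
  drop(bandpass_matrix(matrix(x, ncol = 1L), low, high, tr))
}

#' @export
ideal_bandpass.Volume4D <- function(x, low, high, tr = NULL, mask = NULL) {
  if (is.null(tr)) tr <- x$tr
  mask <- check_mask(mask, x)
  mat <- timeseries_matrix(x, mask)
  put_timeseries(x, mask, bandpass_matrix(mat, low, high, tr))
}

# Core ideal filter on a T x V matrix.
bandpass_matrix <- function(mat, low, high, tr) {
  check_band(low, high)
  n <- nrow(mat)
  nyq <- 1 / (2 * tr)
  # detrend (keep the fitted lines to restore afterwards)
  t0 <- seq_len(n) - (n + 1) / 2
  means <- colMeans(mat)
  slopes <- drop(crossprod(t0, mat)) / sum(t0 * t0)
  lines <- outer(t0, slopes) + rep(means, each = n)
  resid <- mat - lines
  npad <- good_fft_length(n)
  padded <- rbind(resid, matrix(0, npad - n, ncol(mat)))
  freqs <- dft_frequencies(npad, tr)
  keep <- bin_mask(freqs, low, high, nyq)
  keep[1] <- FALSE                              # DC handled by retrend
  if (!any(keep)) stop("ideal_bandpass: no DFT bin falls inside the band; ",
                       "frequency resolution is ", signif(1 / (npad * tr), 3),
                       " Hz")
  ft <- stats::mvfft(padded)
  ft[!keep, ] <- 0
  filtered <- Re(stats::mvfft(ft, inverse = TRUE)) / npad
  filtered[seq_len(n), , drop = FALSE] + lines
}

check_band <- function(low, high) {
  if (!is.finite(low) || low < 0) stop("band: low must be >= 0 Hz")
  if (!is.numeric(high) || high <= low)
    stop("band: need 0 <= low < high (got [", low, ", ", high, "])")
  invisible(TRUE)
}

# full (two-sided) DFT bin frequencies in Hz for length n, spacing 1/(n*tr)
dft_frequencies <- function(n, tr) {
  k <- 0:(n - 1)
  k2 <- ifelse(k <= n / 2, k, k - n)            # signed bin index
  abs(k2) / (n * tr)
}

# closed-interval retention with low-pass / high-pass semantics
bin_mask <- function(freqs, low, high, nyquist) {
  lo_ok <- if (low <= 0) rep(TRUE, length(freqs)) else freqs >= low - 1e-12
  hi_ok <- if (high > nyquist) rep(TRUE, length(freqs))
           else freqs <= high + 1e-12
  lo_ok & hi_ok
}

#' Read a covariate table from a text file
#'
#' Whitespace- or comma-delimited numeric columns, one row per time point
#' (or per subject for group designs). A non-numeric first row is treated as
#' a header.
#'
#' @param path text file path.
#' @return numeric matrix with column names.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("read_covariates: file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  toks <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(toks))))
  df <- utils::read.table(path, header = header, sep = sep)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("read_covariates: non-numeric entries in ", path)
  if (is.null(colnames(m)) || !header)
    colnames(m) <- paste0("cov", seq_len(ncol(m)))
  m
}

check_covariates <- function(covs, n) {
  if (is.null(covs)) return(NULL)
  covs <- as.matrix(covs)
  if (ncol(covs) == 0L) return(NULL)
  if (nrow(covs) != n)
    stop("covariates have ", nrow(covs), " rows but ", n, " are required")
  if (!all(is.finite(covs))) stop("covariates contain non-finite values")
  bad <- apply(covs, 2L, function(cc) all(cc == 0))
  if (any(bad))
    stop("all-zero covariate column(s): ",
         paste(which(bad), collapse = ", "))
  if (is.null(colnames(covs))) colnames(covs) <- paste0("cov", seq_len(ncol(covs)))
  covs
}

# QR of [1 | covs], with a rank check that names collinear columns
design_qr <- function(covs, n) {
  X <- cbind(`(intercept)` = rep(1, n), covs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  qrX
}

#' Regress nuisance covariates out of a 4D volume
#'
#' Per in-mask voxel, replaces the series with the OLS residuals of the
#' regression on an intercept plus the covariate columns (head motion,
#' global mean, white matter, CSF, ...), then adds the voxel's original mean
#' back. Residuals are orthogonal to every covariate column.
#'
#' @param vol a `Volume4D`.
#' @param covs T x p numeric matrix (or `NULL` for a no-op).
#' @param mask optional `Mask`.
#' @return a `Volume4D` of residual series (+ means).
#' @export
regress_covariates <- function(vol, covs, mask = NULL) {
  mask <- check_mask(mask, vol)
  covs <- check_covariates(covs, n_timepoints(vol))
  if (is.null(covs)) return(vol)
  qrX <- design_qr(covs, n_timepoints(vol))
  mat <- timeseries_matrix(vol, mask)
  means <- colMeans(mat)
  res <- qr.resid(qrX, mat) + rep(means, each = nrow(mat))
  put_timeseries(vol, mask, res)
}

#' Build a spherical ROI mask in MNI mm coordinates
#'
#' A voxel belongs to the sphere iff the Euclidean distance from its centre
#' (in mm, via the reference affine) to `center` is at most `radius`.
#'
#' @param center length-3 mm coordinate (e.g. `c(0, -56, 30)` for the PCC).
#' @param radius sphere radius in mm, > 0.
#' @param reference `Volume4D` or `Volume3D` supplying grid and affine.
#' @return a `Mask`.
#' @export
make_sphere_roi <- function(center, radius, reference) {
  if (length(center) != 3L || !all(is.finite(center)))
    stop("make_sphere_roi: center must be a finite mm triple")
  if (!is.finite(radius) || radius <= 0)
    stop("make_sphere_roi: radius must be > 0")
  shape <- spatial_dim(reference)
  ijk <- as.matrix(expand.grid(i = 0:(shape[1] - 1L), j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  mm <- voxel_to_mm(ijk, reference$affine)
  d2 <- (mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2 +
        (mm[, 3] - center[3])^2
  inside <- d2 <= radius^2
  if (!any(inside))
    stop("make_sphere_roi: sphere at (", paste(center, collapse = ", "),
         "), radius ", radius, " mm contains no voxel of the grid")
  brain_mask(array(inside, dim = shape), reference$affine)
}

#' Extract the mean time course of an ROI
#'
#' @param vol a `Volume4D`.
#' @param roi a nonempty `Mask` on the same grid (a single-voxel ROI returns
#'   that voxel's series exactly).
#' @return numeric vector of length T.
#' @export
extract_roi_timecourse <- function(vol, roi) {
  roi <- check_mask(roi, vol)
  mat <- timeseries_matrix(vol, roi)
  rowMeans(mat)
}
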