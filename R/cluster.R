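#' Critical statistic for a two-sided threshold
#'
#' Inverse Student-t CDF at 1 - p/2: the |t| a voxel must exceed to be
#' significant at two-sided level p with the given degrees of freedom
#' (e.g. p = 0.05, df = 19 gives 2.093).
#'
#' @param p two-sided significance level in (0, 1).
#' @param df degrees of freedom >= 1 (`Inf` gives the normal limit).
#' @param kind statistic family; only `"t"` is supported.
#' @return the critical value.
#' @export
critical_stat <- function(p, df, kind = "t") {
  kind <- match.arg(kind, "t")
  if (!is.finite(p) || p <= 0 || p >= 1) stop("critical_stat: p must be in (0,1)")
  if (is.na(df) || df < 1) stop("critical_stat: df must be >= 1")
  stats::qt(1 - p / 2, df = df)
}

#' Convert a statistic map to voxel-wise p-values
#'
#' @param stat a `StatMap` (`t`, `F` or `r`).
#' @param tails `"one"` (positive tail for t/r) or `"two"`; F maps are
#'   always upper-tailed.
#' @return a `Volume3D` of p-values.
#' @export
stat_to_p <- function(stat, tails = c("two", "one")) {
  tails <- match.arg(tails)
  s <- stat$data
  p <- switch(stat$statistic,
    t = if (tails == "two") 2 * stats::pt(abs(s), stat$df, lower.tail = FALSE)
        else stats::pt(s, stat$df, lower.tail = FALSE),
    F = stats::pf(s, stat$df, stat$df2, lower.tail = FALSE),
    r = {
      tt <- s * sqrt(stat$df / pmax(1 - s^2, 1e-300))
      if (tails == "two") 2 * stats::pt(abs(tt), stat$df, lower.tail = FALSE)
      else stats::pt(tt, stat$df, lower.tail = FALSE)
    },
    stop("stat_to_p: unsupported statistic ", stat$statistic))
  p <- pmin(p, 1)
  volume3d(array(p, dim = dim(s)), stat$affine)
}

#' Benjamini-Hochberg FDR threshold over a mask
#'
#' Step-up procedure on the in-mask p-values: with m voxels and sorted
#' p_(1) <= ... <= p_(m), find the largest k with p_(k) <= k q / m;
#' survivors are the voxels with p <= p_(k). A `StatMap` input is first
#' converted to p-values at the requested sidedness.
#'
#' @param pmap `Volume3D` of p-values in \[0, 1\], or a `StatMap`.
#' @param mask a nonempty `Mask`.
#' @param q desired false discovery rate in (0, 1).
#' @param tails sidedness used when converting a `StatMap`.
#' @return list with `threshold` (the p cutoff, `NA` if nothing survives),
#'   `survivors` (a `Mask`), and `n_survivors`.
#' @export
fdr_threshold <- function(pmap, mask, q = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (inherits(pmap, "StatMap")) pmap <- stat_to_p(pmap, tails)
  mask <- check_mask(mask, pmap)
  if (!is.finite(q) || q <= 0 || q >= 1) stop("fdr_threshold: q must be in (0,1)")
  p <- pmap$data[mask$data]
  if (any(p < 0 | p > 1)) stop("fdr_threshold: p-values outside [0, 1]")
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * q / m)
  thr <- if (length(ok)) ps[max(ok)] else NA_real_
  surv <- array(FALSE, dim = dim(pmap$data))
  if (!is.na(thr)) surv[mask$data] <- p <= thr
  list(threshold = thr,
       survivors = brain_mask(surv, pmap$affine),
       n_survivors = sum(surv))
}

# separable Gaussian smoothing of a 3D array; fwhm in mm per axis,
# voxel sizes from the affine; kernel truncated at 3.5 sigma
gaussian_smooth_3d <- function(arr, fwhm_mm, affine) {
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  sigmas <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox   # in voxels
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigmas[ax]
    if (!is.finite(s) || s <= 0) next
    half <- max(1L, ceiling(3.5 * s))
    kern <- stats::dnorm(-half:half, sd = s)
    kern <- kern / sum(kern)
    n <- d[ax]
    band <- matrix(0, n, n)
    for (j in seq_len(n)) {
      lo <- max(1L, j - half); hi <- min(n, j + half)
      w <- kern[(lo - j + half + 1L):(hi - j + half + 1L)]
      band[j, lo:hi] <- w / sum(w)               # renormalised at edges
    }
    m <- aperm(arr, c(ax, setdiff(1:3, ax)))
    dm <- dim(m)
    m <- band %*% matrix(m, dm[1], dm[2] * dm[3])
    arr <- aperm(array(m, dm), order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# connected components of a logical 3D array under 6/18/26-connectivity;
# returns an integer label array (0 = background)
label_components <- function(bin, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  d <- dim(bin)
  idx <- which(bin)
  labels <- array(0L, dim = d)
  if (length(idx) == 0L) return(labels)
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1L) * (d[1] * d[2]) + (pos[, 2] - 1L) * d[1] + pos[, 1]
  lookup <- integer(0)
  lookup[key] <- seq_along(idx)                  # sparse via NA gaps
  offs <- stencil_offsets(connectivity)
  half <- offs[offs[, 1] > 0 |
               (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(half))) {
    o <- half[r, ]
    np <- sweep(pos, 2L, -o)                     # neighbour coordinates
    inside <- np[, 1] >= 1 & np[, 1] <= d[1] &
              np[, 2] >= 1 & np[, 2] <= d[2] &
              np[, 3] >= 1 & np[, 3] <= d[3]
    if (!any(inside)) next
    nk <- (np[inside, 3] - 1L) * (d[1] * d[2]) +
          (np[inside, 2] - 1L) * d[1] + np[inside, 1]
    nb <- rep(NA_integer_, length(nk))
    valid <- nk <= length(lookup)
    nb[valid] <- lookup[nk[valid]]
    hit <- !is.na(nb)
    if (any(hit))
      edges <- rbind(edges, cbind(which(inside)[hit], nb[hit]))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)
  } else {
    g <- igraph::make_graph(as.vector(t(edges)), n = length(idx),
                            directed = FALSE)
    comp <- igraph::components(g)$membership
  }
  labels[idx] <- as.integer(comp)
  labels
}

#' Monte-Carlo cluster-extent simulation (AlphaSim)
#'
#' Estimates, for each cluster size s, the probability under smooth
#' Gaussian noise that a map thresholded at the chosen voxel-wise p contains
#' at least one suprathreshold cluster of >= s voxels. Per iteration: the
#' mask is filled with unit Gaussian noise, smoothed with a Gaussian kernel
#' of the given FWHM, re-standardised within the mask, thresholded at the
#' empirical (1 - voxel_p) within-mask quantile (so the per-voxel rate is
#' exact by construction), and the maximum connected-cluster size recorded.
#'
#' @param mask a nonempty `Mask`.
#' @param fwhm_mm smoothing kernel FWHM in mm (scalar or length-3); 0 means
#'   independent noise.
#' @param voxel_p voxel-wise one-tailed threshold in (0, 1).
#' @param iterations number of Monte-Carlo iterations (>= 100).
#' @param connectivity 6, 18 or 26.
#' @param seed RNG seed, recorded in the output.
#' @return an `AlphaSimTable` data.frame with columns `cluster_size`,
#'   `frequency` (clusters of exactly that size, summed over iterations),
#'   `max_frequency` (iterations whose largest cluster has that size) and
#'   `alpha` (corrected alpha: fraction of iterations whose largest cluster
#'   is >= that size); parameters in `attr(, "parameters")`.
#' @export
alphasim <- function(mask, fwhm_mm = 0, voxel_p = 0.001, iterations = 1000L,
                     connectivity = 26L, seed = 42L) {
  stopifnot(inherits(mask, "Mask"))
  if (!any(mask$data)) stop("alphasim: empty mask")
  if (any(fwhm_mm < 0)) stop("alphasim: FWHM must be >= 0")
  if (iterations < 100L) stop("alphasim: need at least 100 iterations")
  if (voxel_p <= 0 || voxel_p >= 1) stop("alphasim: voxel_p must be in (0,1)")
  fwhm_mm <- rep(fwhm_mm, length.out = 3L)
  d <- dim(mask$data)
  inmask <- mask$data
  n_in <- sum(inmask)
  set.seed(seed)
  max_sizes <- integer(iterations)
  freq <- integer(0)
  smooth <- any(fwhm_mm > 0)
  for (it in seq_len(iterations)) {
    noise <- array(stats::rnorm(prod(d)), dim = d)
    if (smooth) noise <- gaussian_smooth_3d(noise, fwhm_mm, mask$affine)
    vals <- noise[inmask]
    vals <- (vals - mean(vals)) / stats::sd(vals)
    thr <- stats::quantile(vals, 1 - voxel_p, names = FALSE, type = 7)
    supra <- array(FALSE, dim = d)
    supra[inmask] <- vals > thr
    if (!any(supra)) { max_sizes[it] <- 0L; next }
    labels <- label_components(supra, connectivity)
    sizes <- tabulate(labels[labels > 0L])
    max_sizes[it] <- max(sizes)
    for (s in sizes) freq[s] <- (if (s > length(freq) || is.na(freq[s])) 0L
                                 else freq[s]) + 1L
  }
  smax <- max(1L, max(max_sizes))
  freq <- c(freq, integer(max(0L, smax - length(freq))))
  freq[is.na(freq)] <- 0L
  sizes <- seq_len(smax)
  alpha <- vapply(sizes, function(s) mean(max_sizes >= s), 1.0)
  out <- data.frame(cluster_size = sizes,
                    frequency = freq[sizes],
                    max_frequency = vapply(sizes, function(s)
                      sum(max_sizes == s), 1L),
                    alpha = alpha)
  attr(out, "parameters") <- list(
    fwhm_mm = fwhm_mm, voxel_p = voxel_p, iterations = iterations,
    connectivity = connectivity, seed = seed, n_mask_voxels = n_in)
  class(out) <- c("AlphaSimTable", "data.frame")
  out
}

#' Report suprathreshold clusters of a statistic map
#'
#' Connected components of the voxels exceeding the threshold (positive,
#' negative, or both sides), filtered by a minimum size, sorted by voxel
#' count (descending). Peak = the member voxel with maximum |intensity|;
#' its mm coordinates come from the affine; cluster volume = voxel count
#' times the voxel volume.
#'
#' @param stat a `StatMap` or `Volume3D`.
#' @param voxel_threshold statistic cutoff (applied as > threshold).
#' @param min_cluster_voxels minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26.
#' @param sidedness `"pos"`, `"neg"` or `"both"`.
#' @param mask optional `Mask`.
#' @return a `ClusterTable` data.frame: `cluster_id`, `n_voxels`,
#'   `volume_mm3`, `peak_x/y/z` (mm), `peak_intensity` (possibly empty).
#' @export
cluster_report <- function(stat, voxel_threshold, min_cluster_voxels = 1L,
                           connectivity = 26L,
                           sidedness = c("both", "pos", "neg"),
                           mask = NULL) {
  sidedness <- match.arg(sidedness)
  if (!is.finite(voxel_threshold)) stop("cluster_report: threshold not finite")
  mask <- check_mask(mask, stat, require_nonempty = FALSE)
  s <- stat$data
  supra <- switch(sidedness,
                  pos = s > voxel_threshold,
                  neg = s < -voxel_threshold,
                  both = abs(s) > voxel_threshold)
  supra <- supra & mask$data
  empty <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      peak_intensity = numeric(0))
  class(empty) <- c("ClusterTable", "data.frame")
  if (!any(supra)) return(empty)
  labels <- label_components(supra, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_cluster_voxels)
  if (!length(keep)) return(empty)
  vv <- voxel_volume_mm3(stat$affine)
  rows <- lapply(keep, function(lab) {
    members <- which(labels == lab)
    vals <- s[members]
    peak <- members[which.max(abs(vals))]
    ijk <- arrayInd(peak, dim(s)) - 1L           # 0-based voxel index
    mm <- voxel_to_mm(as.numeric(ijk), stat$affine)
    data.frame(n_voxels = length(members), volume_mm3 = length(members) * vv,
               peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
               peak_intensity = s[peak])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_voxels), , drop = FALSE]
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("ClusterTable", "data.frame")
  out
}
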