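#' Specification for a synthetic resting-state 4D volume
#'
#' Describes the emulated acquisition (grid, TR, series length) and the
#' planted structure: "networks" (voxel regions sharing a sinusoid of one
#' frequency and phase, so they are mutually correlated and carry in-band
#' amplitude), per-voxel linear drift, white Gaussian noise, and a standard
#' nuisance set (one global, one white-matter-like, one CSF-like and six
#' motion-like series) that in-mask voxels load on. Everything is
#' deterministic under `seed`.
#'
#' @param grid spatial dimensions (default 16 x 16 x 16 at 3 mm isotropic).
#' @param t number of time points (default 120).
#' @param tr repetition time in seconds (default 2, so Nyquist = 0.25 Hz
#'   and the padded frequency resolution is about 0.004 Hz).
#' @param seed RNG seed fixing the whole stream.
#' @param baseline mean signal level added everywhere.
#' @param noise_sd white-noise standard deviation.
#' @param drift_slope_range per-voxel drift slope drawn uniformly from this
#'   interval (signal units per volume).
#' @param networks list of planted components; each a list with `region`
#'   (list(lo, hi) voxel-index corners, 1-based), `freq_hz`, `amplitude`
#'   and optional `shared_noise_sd` (common noise that raises local
#'   concordance, for a high-ReHo region).
#' @param nuisance_loading loading of every in-mask voxel on each nuisance
#'   series (0 disables nuisance structure).
#' @return a `FixtureSpec`.
#' @export
fixture_spec <- function(grid = c(16L, 16L, 16L), t = 120L, tr = 2,
                         seed = 1L, baseline = 100, noise_sd = 1,
                         drift_slope_range = c(-0.05, 0.05),
                         networks = NULL,
                         nuisance_loading = 0.3) {
  grid <- as.integer(grid)
  if (is.null(networks)) networks <- default_networks(grid)
  nyq <- 1 / (2 * tr)
  for (nw in networks) {
    for (b in nw$region)
      if (any(b$lo < 1) || any(b$hi > grid) || any(b$lo > b$hi))
        stop("fixture_spec: region box outside the grid")
    if (nw$freq_hz >= nyq)
      stop("fixture_spec: planted frequency ", nw$freq_hz,
           " Hz is at or above Nyquist (", nyq, " Hz)")
    if (nw$amplitude < 0) stop("fixture_spec: amplitudes must be >= 0")
  }
  structure(list(grid = as.integer(grid), t = as.integer(t), tr = tr,
                 seed = as.integer(seed), baseline = baseline,
                 noise_sd = noise_sd, drift_slope_range = drift_slope_range,
                 networks = networks, nuisance_loading = nuisance_loading),
            class = "FixtureSpec")
}

# the default planted structure: a two-blob 0.04 Hz "network" (seed-FC and
# ALFF recovery) and a compact high-concordance region (ReHo recovery);
# box corners scale with the grid (reference layout is 16^3)
default_networks <- function(grid = c(16L, 16L, 16L)) {
  sc <- function(v) pmax(1L, pmin(grid, as.integer(round(v * grid / 16))))
  box <- function(lo, hi) list(lo = sc(lo), hi = sc(hi))
  list(
    network = list(region = list(box(c(3, 3, 3), c(5, 5, 5)),
                                 box(c(11, 11, 11), c(13, 13, 13))),
                   freq_hz = 0.04, amplitude = 3),
    reho_region = list(region = list(box(c(3, 11, 3), c(6, 14, 6))),
                       freq_hz = 0.05, amplitude = 4, shared_noise_sd = 1))
}

region_mask_array <- function(boxes, grid) {
  m <- array(FALSE, dim = grid)
  for (b in boxes)
    m[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- TRUE
  m
}

default_affine <- function(grid, vox = 3) {
  aff <- diag(c(vox, vox, vox, 1))
  aff[1:3, 4] <- -(grid - 1) / 2 * vox
  aff
}

# smooth unit-variance nuisance series: white noise low-passed by a short
# moving average, then standardised
smooth_series <- function(t, width = 8L) {
  x <- stats::filter(stats::rnorm(t + 2L * width), rep(1 / width, width),
                     sides = 2L)
  x <- x[(width + 1L):(width + t)]
  as.numeric((x - mean(x)) / stats::sd(x))
}

#' Generate a synthetic 4D resting-state volume with known ground truth
#'
#' @param spec a `FixtureSpec`.
#' @return list with `volume` (a `Volume4D`), `truth` (region masks as
#'   `Mask`, planted frequencies/amplitudes/phases, drift slopes, nuisance
#'   matrix and loadings) and `mask` (all-true analysis mask).
#' @export
make_rs_volume <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  grid <- spec$grid; tt <- spec$t; tr <- spec$tr
  nv <- prod(grid)
  aff <- default_affine(grid)
  time_s <- (seq_len(tt) - 1L) * tr

  dat <- matrix(stats::rnorm(nv * tt, sd = spec$noise_sd), nv, tt)
  dat <- dat + spec$baseline
  slopes <- stats::runif(nv, spec$drift_slope_range[1],
                         spec$drift_slope_range[2])
  dat <- dat + outer(slopes, seq_len(tt) - (tt + 1) / 2)

  truth <- list(networks = list(), drift_slopes = slopes)
  for (nm in names(spec$networks)) {
    nw <- spec$networks[[nm]]
    sel <- as.vector(region_mask_array(nw$region, grid))
    phase <- stats::runif(1, 0, 2 * pi)          # shared within the network
    sig <- nw$amplitude * sin(2 * pi * nw$freq_hz * time_s + phase)
    dat[sel, ] <- dat[sel, ] + rep(sig, each = sum(sel))
    if (!is.null(nw$shared_noise_sd) && nw$shared_noise_sd > 0) {
      common <- stats::rnorm(tt, sd = nw$shared_noise_sd)
      dat[sel, ] <- dat[sel, ] + rep(common, each = sum(sel))
    }
    truth$networks[[nm]] <- list(
      mask = brain_mask(region_mask_array(nw$region, grid), aff),
      freq_hz = nw$freq_hz, amplitude = nw$amplitude, phase = phase)
  }

  nuis <- NULL
  if (spec$nuisance_loading != 0) {
    nuis <- cbind(global = smooth_series(tt),
                  wm = smooth_series(tt),
                  csf = smooth_series(tt),
                  sapply(1:6, function(i) smooth_series(tt, width = 16L)))
    colnames(nuis)[4:9] <- paste0("motion", 1:6)
    loading <- spec$nuisance_loading
    dat <- dat + loading * matrix(rowSums(nuis), nv, tt, byrow = TRUE)
    truth$nuisance <- list(series = nuis, loading = loading)
  }

  vol <- volume4d(array(dat, dim = c(grid, tt)), aff, tr)
  list(volume = vol, truth = truth,
       mask = brain_mask(array(TRUE, dim = grid), aff))
}

#' Generate per-subject 3D maps with a planted regional effect
#'
#' Subject map = `baseline` + `effect_size` inside the effect region +
#' independent Gaussian noise, optionally tied to a per-subject regressor
#' (`effect_size * regressor[s]` inside the region) for correlation-map
#' checks.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param effect_region a `Mask`, or `NULL` for a default central box on a
#'   16^3 grid.
#' @param effect_size mean shift inside the region (0 gives pure null maps).
#' @param noise_sd per-voxel noise standard deviation.
#' @param seed RNG seed.
#' @param baseline constant background level.
#' @param regressor optional per-subject vector scaling the effect.
#' @return list with `maps` (list of `Volume3D`), `truth` (region mask,
#'   effect size, regressor).
#' @export
make_group_maps <- function(n_subjects, effect_region = NULL,
                            effect_size = 0, noise_sd = 1, seed = 1L,
                            baseline = 1, regressor = NULL) {
  if (n_subjects < 2L) stop("make_group_maps: need at least 2 subjects")
  set.seed(seed)
  if (is.null(effect_region)) {
    grid <- c(16L, 16L, 16L)
    effect_region <- brain_mask(
      region_mask_array(list(list(lo = c(6, 6, 6), hi = c(10, 10, 10))), grid),
      default_affine(grid))
  }
  grid <- dim(effect_region$data)
  ind <- as.numeric(effect_region$data)
  if (!is.null(regressor) && length(regressor) != n_subjects)
    stop("make_group_maps: regressor length != n_subjects")
  maps <- lapply(seq_len(n_subjects), function(s) {
    scale <- if (is.null(regressor)) 1 else regressor[s]
    m <- baseline + effect_size * scale * ind +
      stats::rnorm(prod(grid), sd = noise_sd)
    volume3d(array(m, dim = grid), effect_region$affine)
  })
  list(maps = maps,
       truth = list(region = effect_region, effect_size = effect_size,
                    noise_sd = noise_sd, regressor = regressor))
}
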