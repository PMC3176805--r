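#' @title In-memory volume containers
#' @description `volume4d()`, `volume3d()` and `brain_mask()` are the
#'   lightweight containers every restkit operation works on: a plain R array
#'   plus the voxel-to-mm affine and (for 4D data) the repetition time.
#' @name volumes
NULL

#' Construct a 4D BOLD volume
#'
#' @param data numeric 4D array, X x Y x Z x T.
#' @param affine 4x4 voxel-index (0-based) to mm transform.
#' @param tr repetition time in seconds (sampling interval of the series).
#' @return An object of class `Volume4D` with fields `data`, `affine`, `tr`.
#' @export
volume4d <- function(data, affine = diag(4), tr = 2) {
  data <- as_array(data)
  if (length(dim(data)) != 4L)
    stop("volume4d: data must be a 4D array, got ", length(dim(data)), "D")
  if (dim(data)[4] < 2L)
    stop("volume4d: need at least 2 time points, got ", dim(data)[4])
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("volume4d: tr must be a single positive number (seconds)")
  check_affine(affine)
  structure(list(data = data, affine = affine, tr = tr), class = "Volume4D")
}

#' Construct a 3D volume (a single map)
#'
#' @param data numeric 3D array.
#' @param affine 4x4 voxel-index to mm transform.
#' @return An object of class `Volume3D`.
#' @export
volume3d <- function(data, affine = diag(4)) {
  data <- as_array(data)
  if (length(dim(data)) != 3L)
    stop("volume3d: data must be a 3D array, got ", length(dim(data)), "D")
  check_affine(affine)
  structure(list(data = data, affine = affine), class = "Volume3D")
}

#' Construct a binary analysis mask
#'
#' @param data logical (or numeric, binarised at nonzero) 3D array.
#' @param affine 4x4 transform shared with the reference volume.
#' @return An object of class `Mask` whose `data` is logical.
#' @export
brain_mask <- function(data, affine = diag(4)) {
  data <- as_array(data)
  if (length(dim(data)) != 3L)
    stop("brain_mask: data must be 3D")
  check_affine(affine)
  m <- array(as.logical(data != 0), dim = dim(data))
  structure(list(data = m, affine = affine), class = "Mask")
}

as_array <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x))
  storage.mode(a) <- "double"
  a
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (!all(is.finite(affine)))
    stop("affine contains non-finite entries")
  d <- det(affine)
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("affine is singular")
  invisible(affine)
}

spatial_dim <- function(vol) {
  d <- dim(vol$data)
  if (length(d) == 4L) d[1:3] else d
}

n_timepoints <- function(vol) {
  d <- dim(vol$data)
  if (length(d) != 4L) stop("not a 4D volume")
  d[4]
}

#' Voxel indices to mm coordinates
#'
#' Voxel indices are 0-based; mm coordinates are `affine %*% c(i, j, k, 1)`.
#'
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @param affine 4x4 transform.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(ijk, affine) {
  ijk <- rbind_coords(ijk)
  mm <- cbind(ijk, 1) %*% t(affine)
  mm[, 1:3, drop = FALSE]
}

#' mm coordinates to (fractional) 0-based voxel indices
#' @param mm n x 3 matrix (or length-3 vector) of mm coordinates.
#' @param affine 4x4 transform.
#' @return n x 3 matrix of fractional voxel indices.
#' @export
mm_to_voxel <- function(mm, affine) {
  mm <- rbind_coords(mm)
  ijk <- cbind(mm, 1) %*% t(solve(affine))
  ijk[, 1:3, drop = FALSE]
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  x
}

# volume of one voxel in mm^3, from the spatial 3x3 block
voxel_volume_mm3 <- function(affine) abs(det(affine[1:3, 1:3]))

#' Align a 3D map to a reference grid as a mask
#'
#' Binarises a 3D map (nonzero, or above `threshold` when given) against the
#' grid of a reference volume. Resampling is out of scope: the shapes must
#' already match.
#'
#' @param mask a `Volume3D` (or `Mask`).
#' @param reference a `Volume4D` or `Volume3D` providing grid and affine.
#' @param threshold optional: voxels with value > threshold are kept
#'   (default: any nonzero voxel).
#' @return a `Mask` carrying the reference affine.
#' @export
align_mask <- function(mask, reference, threshold = NULL) {
  ms <- spatial_dim(mask)
  rs <- spatial_dim(reference)
  if (!all(ms == rs))
    stop(sprintf("align_mask: mask grid %s does not match reference grid %s",
                 paste(ms, collapse = "x"), paste(rs, collapse = "x")))
  keep <- if (is.null(threshold)) mask$data != 0 else mask$data > threshold
  brain_mask(array(keep, dim = ms), reference$affine)
}

#' @export
print.Volume4D <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<Volume4D %dx%dx%d, T=%d, tr=%gs>\n", d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' @export
print.Volume3D <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<Volume3D %dx%dx%d>\n", d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.Mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<Mask %dx%dx%d, %d voxels in mask>\n", d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

# Internal: mask used when the caller passes NULL (everything in-mask)
default_mask <- function(reference) {
  brain_mask(array(TRUE, dim = spatial_dim(reference)), reference$affine)
}

check_mask <- function(mask, reference, require_nonempty = TRUE) {
  if (is.null(mask)) return(default_mask(reference))
  if (!inherits(mask, "Mask")) mask <- align_mask(mask, reference)
  if (!all(spatial_dim(mask) == spatial_dim(reference)))
    stop("mask grid does not match the reference volume")
  if (require_nonempty && !any(mask$data))
    stop("mask is empty: no in-mask voxels")
  mask
}
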