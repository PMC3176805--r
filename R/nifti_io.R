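#' Read a 3D or 4D volume from NIfTI-1 or ANALYZE 7.5
#'
#' Accepts `.nii`, `.nii.gz` and `.hdr`/`.img` pairs (NIfTI pair or ANALYZE
#' 7.5; ANALYZE carries no full affine, so the transform is synthesised from
#' voxel sizes and origin, RAS-positive).
#'
#' @param path path to a `.nii`, `.nii.gz`, `.hdr` or `.img` file.
#' @param tr optional repetition time override in seconds. An explicit value
#'   always wins over the header time step; a 4D file whose header time step
#'   is not positive *requires* it.
#' @return `Volume4D` for 4D files, `Volume3D` for 3D files.
#' @export
read_volume <- function(path, tr = NULL) {
  if (!file.exists(path) && !file.exists(paste0(path, ".gz")))
    stop("read_volume: file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: cannot read '", path,
                                           "': ", conditionMessage(e)))
  hdr <- RNifti::niftiHeader(img)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  nd <- length(dim(a))
  if (nd == 3L) {
    volume3d(a, aff)
  } else if (nd == 4L) {
    header_tr <- hdr$pixdim[5]
    # the NIfTI library normalises a zero time step to 1 on load, so consult
    # the on-disk field to enforce the explicit-tr contract
    raw_tr <- raw_header_time_step(path)
    if (is.null(tr)) {
      if (!is.finite(header_tr) || header_tr <= 0 ||
          (!is.na(raw_tr) && raw_tr <= 0))
        stop("read_volume: 4D file has non-positive header time step; ",
             "pass an explicit tr")
      tr <- header_tr
    }
    volume4d(a, aff, tr = tr)
  } else {
    stop("read_volume: unsupported dimensionality ", nd, " in ", path)
  }
}

#' Write a volume as NIfTI-1 (.nii) or .hdr/.img pair(s)
#'
#' `format = "pair"` on a 4D volume splits the series into one 3D
#' `.hdr`/`.img` pair per time point, suffixed `_0001`, `_0002`, ...
#' Header voxel sizes are derived from the affine; the repetition time is
#' stored in the header time step.
#'
#' @param vol a `Volume4D`, `Volume3D` or `Mask`.
#' @param path output path; the extension may be omitted.
#' @param format `"nii"` (single file) or `"pair"` (`.hdr`/`.img`).
#' @param datatype on-disk datatype, `"double"` (default) or `"float"`.
#' @return invisibly, the path(s) written.
#' @export
write_volume <- function(vol, path, format = c("nii", "pair"),
                         datatype = "double") {
  format <- match.arg(format)
  check_affine(vol$affine)
  base <- sub("\\.(nii\\.gz|nii|hdr|img)$", "", path)
  is4d <- inherits(vol, "Volume4D")
  data <- vol$data
  if (inherits(vol, "Mask")) storage.mode(data) <- "double"

  if (format == "pair" && is4d) {
    tt <- dim(data)[4]
    paths <- character(tt)
    for (t in seq_len(tt)) {
      p <- sprintf("%s_%04d.hdr", base, t)
      write_one(data[, , , t, drop = TRUE], vol$affine, NA_real_, p, datatype)
      paths[t] <- p
    }
    return(invisible(paths))
  }
  ext <- if (format == "nii") {
    if (grepl("\\.nii\\.gz$", path)) ".nii.gz" else ".nii"
  } else ".hdr"
  p <- paste0(base, ext)
  write_one(data, vol$affine, if (is4d) vol$tr else NA_real_, p, datatype)
  invisible(p)
}

# the stored (unnormalised) pixdim[4] of a NIfTI-1/ANALYZE header, or NA
raw_header_time_step <- function(path) {
  hdr_path <- sub("\\.img(\\.gz)?$", ".hdr\\1", path)
  if (!file.exists(hdr_path)) {
    if (file.exists(paste0(hdr_path, ".gz"))) hdr_path <- paste0(hdr_path, ".gz")
    else if (!file.exists(path)) return(NA_real_)
    else hdr_path <- path
  }
  con <- gzfile(hdr_path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- if (identical(sz, 348L)) "little" else "big"
  readBin(con, "raw", 72L)                      # skip to pixdim[0]
  pd <- readBin(con, "double", 8L, size = 4L, endian = endian)
  if (length(pd) < 5L) return(NA_real_)
  pd[5]
}

write_one <- function(data, affine, tr, path, datatype) {
  img <- RNifti::asNifti(data, datatype = datatype)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  pd <- c(1, vox, if (is.finite(tr)) tr else 0, 0, 0, 0)
  img$pixdim <- pd
  img$xyzt_units <- 10L  # mm + s
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  withCallingHandlers(
    RNifti::writeNifti(img, path, datatype = datatype),
    warning = function(w) {
      stop("write_volume: cannot write '", path, "': ",
           conditionMessage(w), call. = FALSE)
    })
  if (!file.exists(path))
    stop("write_volume: output '", path, "' was not created")
  path
}

#' Plan spatial blocks that bound peak memory
#'
#' Splits the spatial grid into contiguous boxes of at most
#' `max_voxels_per_block` voxels each, covering the grid exactly once.
#' Working block-by-block trades time for space, so very long series fit in
#' memory; neighbourhood metrics additionally pad blocks by an `overlap`
#' margin so results away from the grid border are identical to a
#' whole-volume run.
#'
#' @param max_voxels_per_block positive integer.
#' @return an object of class `BlockPlan`.
#' @export
block_plan <- function(max_voxels_per_block) {
  if (!is.numeric(max_voxels_per_block) || max_voxels_per_block < 1)
    stop("block_plan: max_voxels_per_block must be >= 1")
  structure(list(max_voxels = as.integer(max_voxels_per_block)),
            class = "BlockPlan")
}

# Partition a 3D shape into index boxes honouring the voxel budget.
# Splits along z first, then y, then x.
block_ranges <- function(shape, max_voxels) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  split_axis <- function(n, per) {
    per <- max(1L, min(n, as.integer(per)))
    starts <- seq.int(1L, n, by = per)
    lapply(starts, function(s) c(s, min(n, s + per - 1L)))
  }
  zs <- split_axis(nz, max_voxels %/% max(1L, nx * ny))
  ys <- split_axis(ny, max_voxels %/% max(1L, nx))
  xs <- split_axis(nx, max_voxels)
  need_y <- nx * ny > max_voxels
  need_x <- nx > max_voxels
  out <- list()
  for (zr in zs)
    for (yr in if (need_y) ys else list(c(1L, ny)))
      for (xr in if (need_x) xs else list(c(1L, nx)))
        out[[length(out) + 1L]] <- list(x = xr, y = yr, z = zr)
  out
}

#' Iterate over spatial blocks of a 4D volume
#'
#' @param vol a `Volume4D`.
#' @param plan a `BlockPlan`.
#' @param overlap non-negative integer margin (voxels) added on every side;
#'   required for neighbourhood-dependent metrics (use the stencil radius).
#' @return a list of blocks, each a list with `vol` (`Volume4D` slab whose
#'   affine is translated to the slab origin), `core` (index ranges of the
#'   non-overlap region *within* the slab) and `dest` (the same region in the
#'   full grid).
#' @export
iter_blocks <- function(vol, plan, overlap = 0L) {
  stopifnot(inherits(plan, "BlockPlan"), overlap >= 0)
  shape <- spatial_dim(vol)
  rngs <- block_ranges(shape, plan$max_voxels)
  lapply(rngs, function(r) {
    lo <- pmax(c(r$x[1], r$y[1], r$z[1]) - overlap, 1L)
    hi <- pmin(c(r$x[2], r$y[2], r$z[2]) + overlap, shape)
    sub <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE]
    shift <- diag(4); shift[1:3, 4] <- lo - 1L
    core <- list(x = (r$x[1]:r$x[2]) - lo[1] + 1L,
                 y = (r$y[1]:r$y[2]) - lo[2] + 1L,
                 z = (r$z[1]:r$z[2]) - lo[3] + 1L)
    dest <- list(x = r$x[1]:r$x[2], y = r$y[1]:r$y[2], z = r$z[1]:r$z[2])
    list(vol = volume4d(sub, vol$affine %*% shift, vol$tr),
         origin = lo, core = core, dest = dest)
  })
}

#' Apply a map-producing function block-by-block and reassemble
#'
#' The contract: for any voxel-independent `fun`, the assembled map is
#' bit-identical to `fun` on the whole volume; for neighbourhood metrics the
#' same holds away from the grid border when `overlap` is at least the
#' stencil radius.
#'
#' @param vol a `Volume4D`.
#' @param plan a `BlockPlan`.
#' @param fun `function(block_vol, block_mask) -> Volume3D | MetricMap | 3D array`.
#' @param mask optional `Mask`, subset per block and passed to `fun`.
#' @param overlap margin in voxels (see [iter_blocks()]).
#' @return a `Volume3D` on the full grid.
#' @export
block_apply <- function(vol, plan, fun, mask = NULL, overlap = 0L) {
  mask <- check_mask(mask, vol, require_nonempty = FALSE)
  out <- array(0, dim = spatial_dim(vol))
  for (blk in iter_blocks(vol, plan, overlap)) {
    bd <- spatial_dim(blk$vol)
    lo <- blk$origin
    sub_mask <- brain_mask(
      mask$data[lo[1] - 1L + seq_len(bd[1]), lo[2] - 1L + seq_len(bd[2]),
                lo[3] - 1L + seq_len(bd[3]), drop = FALSE],
      blk$vol$affine)
    res <- fun(blk$vol, sub_mask)
    rdata <- if (is.list(res)) res$data else res
    out[blk$dest$x, blk$dest$y, blk$dest$z] <-
      rdata[blk$core$x, blk$core$y, blk$core$z]
  }
  volume3d(out, vol$affine)
}
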