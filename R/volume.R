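#' 3-D scalar image volume with a voxel-to-world affine
#'
#' The shared container for all images in the pipeline: a 3-D numeric array
#' plus a 4x4 voxel-to-world affine. World coordinates are millimetres.
#' Voxel indices are 0-based in the affine convention; the world position of
#' voxel `(i, j, k)` (0-based) is `affine %*% c(i + 0.5, j + 0.5, k + 0.5, 1)`,
#' i.e. the affine maps voxel *centers*.
#'
#' @param data 3-D numeric array of intensities.
#' @param affine 4x4 voxel-to-world matrix; if `NULL`, built from
#'   `voxel_size_mm` and `origin_mm`.
#' @param voxel_size_mm length-3 positive voxel edge lengths (mm).
#' @param origin_mm world position of the corner of voxel (0,0,0) (mm).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, affine = NULL, voxel_size_mm = c(1, 1, 1),
                         origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (is.null(affine)) {
    stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
    affine <- diag(c(voxel_size_mm, 1))
    affine[1:3, 4] <- origin_mm
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  structure(list(data = data, affine = affine,
                 inv_affine = solve(affine)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("image_volume: %d x %d x %d voxels, voxel size %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Voxel edge lengths of a volume (mm)
#' @param vol an `image_volume`.
#' @return length-3 numeric vector.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Convert 0-based voxel indices to world coordinates (voxel centers)
#' @param vol an `image_volume`.
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind3(ijk)
  h <- cbind(ijk + 0.5, 1)
  out <- h %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

#' Convert world coordinates to continuous 0-based voxel indices
#' @param vol an `image_volume`.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of continuous 0-based indices (voxel-center convention).
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind3(xyz)
  h <- cbind(xyz, 1)
  out <- h %*% t(vol$inv_affine)
  out[, 1:3, drop = FALSE] - 0.5
}

# coerce a length-3 vector or n x 3 matrix to an n x 3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
}

#' World coordinates of all voxel centers
#' @param vol an `image_volume`.
#' @return (prod(dim)) x 3 matrix, fastest index first.
#' @keywords internal
all_voxel_centers <- function(vol) {
  d <- dim(vol$data)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  voxel_to_world(vol, ijk)
}

#' Sample a volume at world points
#'
#' Trilinear or nearest-neighbour interpolation; points outside the grid get
#' `outside` (default `NA`).
#'
#' @param vol an `image_volume`.
#' @param xyz n x 3 world coordinates (mm).
#' @param interp `"trilinear"` or `"nearest"`.
#' @param outside fill value for points outside the grid.
#' @return numeric vector of length n.
#' @export
sample_volume <- function(vol, xyz, interp = c("trilinear", "nearest"),
                          outside = NA_real_) {
  interp <- match.arg(interp)
  idx <- world_to_voxel(vol, xyz)            # continuous 0-based
  d <- dim(vol$data)
  out <- rep(outside, nrow(idx))
  if (interp == "nearest") {
    i <- round(idx) + 1                       # 1-based
    ok <- i[, 1] >= 1 & i[, 1] <= d[1] & i[, 2] >= 1 & i[, 2] <= d[2] &
      i[, 3] >= 1 & i[, 3] <= d[3]
    if (any(ok))
      out[ok] <- vol$data[cbind(i[ok, 1], i[ok, 2], i[ok, 3])]
    return(out)
  }
  # trilinear: clamp to the valid interpolation cube
  f <- idx + 1                                # 1-based continuous
  ok <- f[, 1] >= 1 & f[, 1] <= d[1] & f[, 2] >= 1 & f[, 2] <= d[2] &
    f[, 3] >= 1 & f[, 3] <= d[3]
  if (!any(ok)) return(out)
  f <- f[ok, , drop = FALSE]
  i0 <- pmin(pmax(floor(f), 1), rep(d - 1L, each = nrow(f)))
  w <- f - i0
  dat <- vol$data
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- (i0[, 1]) + (i0[, 2] - 1) * n1 + (i0[, 3] - 1) * n12
  v000 <- dat[base];            v100 <- dat[base + 1]
  v010 <- dat[base + n1];       v110 <- dat[base + n1 + 1]
  v001 <- dat[base + n12];      v101 <- dat[base + n12 + 1]
  v011 <- dat[base + n1 + n12]; v111 <- dat[base + n1 + n12 + 1]
  wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
  out[ok] <-
    v000 * (1 - wx) * (1 - wy) * (1 - wz) + v100 * wx * (1 - wy) * (1 - wz) +
    v010 * (1 - wx) * wy * (1 - wz)       + v110 * wx * wy * (1 - wz) +
    v001 * (1 - wx) * (1 - wy) * wz       + v101 * wx * (1 - wy) * wz +
    v011 * (1 - wx) * wy * wz             + v111 * wx * wy * wz
  out
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers over RNifti. The NIfTI sform holds the voxel-to-world affine
#' in the voxel-center convention used throughout the package.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol an `image_volume`.
#' @return `read_volume` returns an `image_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  # RNifti's xform maps 0-based indices to world; convert center convention
  aff <- vol$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep(0.5, 3)
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  aff <- rbind(aff, c(0, 0, 0, 1))[1:4, 1:4]
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% rep(0.5, 3)
  image_volume(array(as.numeric(img), dim = dim(img)), affine = aff)
}
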