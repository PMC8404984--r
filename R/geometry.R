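#' Volume geometry: matrix size plus voxel-to-mm affine
#'
#' A `vol_geometry` ties a 3-D matrix size to a 4x4 affine mapping 0-based
#' voxel indices `(i, j, k)` to physical RAS+ coordinates in millimetres, the
#' NIfTI convention. All physical computation in the package (coordinate
#' normalization, harmonic bases, convex hulls, fit re-application) is done in
#' mm so that prescan and target grids of different resolution and field of
#' view align.
#'
#' @param matrix_size integer vector of length 3, voxels per axis (all >= 1).
#' @param affine 4x4 numeric matrix; upper-left 3x3 must be invertible and the
#'   last row `(0, 0, 0, 1)`.
#' @return An object of class `vol_geometry` with elements `matrix_size` and
#'   `affine`.
#' @examples
#' g <- vol_geometry(c(32, 32, 32), diag(c(8, 8, 8, 1)))
#' n_voxels(g)
#' @export
vol_geometry <- function(matrix_size, affine) {
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) != 3L || any(matrix_size < 1L))
    stop("matrix_size must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("affine upper-left 3x3 is singular")
  structure(list(matrix_size = matrix_size, affine = affine),
            class = "vol_geometry")
}

#' @export
print.vol_geometry <- function(x, ...) {
  cat("vol_geometry:", paste(x$matrix_size, collapse = " x "), "voxels\n")
  cat("voxel size (mm):",
      paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 4), collapse = " x "),
      "\n")
  invisible(x)
}

#' Number of voxels in a geometry
#' @param geometry a [vol_geometry()].
#' @return integer voxel count.
#' @export
n_voxels <- function(geometry) prod(geometry$matrix_size)

#' A centred isotropic geometry
#'
#' Convenience constructor for a cubic grid of `n` voxels per axis with the
#' given isotropic voxel size, centred on the physical origin (the volume
#' centre maps to 0 mm).
#'
#' @param n voxels per axis.
#' @param voxel_mm isotropic voxel size in mm.
#' @return a [vol_geometry()].
#' @export
centered_geometry <- function(n, voxel_mm) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * (n - 1) / 2
  vol_geometry(rep(n, 3L), aff)
}

#' 0-based voxel index grid in raster order
#'
#' Raster order is x fastest, then y, then z; this is the fixed documented
#' vectorization order for every per-voxel array in the package.
#'
#' @param geometry a [vol_geometry()].
#' @return n_voxels x 3 integer matrix of 0-based indices.
#' @export
voxel_index_grid <- function(geometry) {
  d <- geometry$matrix_size
  cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
}

#' Map 0-based voxel indices to mm coordinates
#' @param geometry a [vol_geometry()].
#' @param ijk n x 3 matrix of 0-based voxel indices (defaults to the full grid
#'   in raster order).
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(geometry, ijk = voxel_index_grid(geometry)) {
  ijk <- rbind(t(ijk), 1)
  out <- t(geometry$affine %*% ijk)[, 1:3, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Map mm coordinates to (fractional) 0-based voxel indices
#' @param geometry a [vol_geometry()].
#' @param xyz n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of fractional voxel indices.
#' @export
mm_to_voxel <- function(geometry, xyz) {
  inv <- solve(geometry$affine)
  t(inv %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' Dimensionless voxel coordinates for basis evaluation
#'
#' Returns `(mm - c0) / r0` for every voxel in raster order (x fastest). The
#' same `(c0, r0)` pair stored with a harmonic fit reproduces identical
#' coordinates when the fit is re-evaluated on any geometry.
#'
#' @param geometry a [vol_geometry()].
#' @param c0 length-3 centre in mm.
#' @param r0 positive scale in mm.
#' @return n_voxels x 3 numeric matrix, dimensionless.
#' @export
voxel_coordinates <- function(geometry, c0 = c(0, 0, 0), r0 = 1) {
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("r0 must be a positive scalar")
  mm <- voxel_to_mm(geometry)
  sweep(mm, 2, as.numeric(c0)) / r0
}
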