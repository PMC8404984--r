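#' Convex hull of fitted voxels
#'
#' Polynomial bases extrapolate poorly, so fitted sensitivities are trusted
#' only inside the convex hull (in mm coordinates) of the voxels used in the
#' least-squares fit; exterior target voxels are evaluated at the closest
#' point on the hull surface.
#'
#' @param voxels either an [snr_threshold_mask()], a logical vector over the
#'   geometry's voxels, or a vector of linear voxel indices.
#' @param geometry the [vol_geometry()] the voxels live on.
#' @return object of class `hull3d`: `vertices` (v x 3 mm coordinates),
#'   `faces` (f x 3 indices into `vertices`), `normals`, `offsets`.
#' @export
build_hull <- function(voxels, geometry) {
  if (inherits(voxels, "snr_mask")) voxels <- voxels$mask
  idx <- if (is.logical(voxels)) which(voxels) else as.integer(voxels)
  if (length(idx) < 4) stop("convex hull needs at least 4 masked voxels")
  pts <- voxel_to_mm(geometry)[idx, , drop = FALSE]
  qh <- .quickhull3_cpp(pts)
  vidx <- qh$vertex_indices
  remap <- integer(nrow(pts))
  remap[vidx] <- seq_along(vidx)
  faces <- matrix(remap[qh$faces], ncol = 3)
  structure(list(vertices = pts[vidx, , drop = FALSE],
                 faces = faces,
                 normals = qh$normals,
                 offsets = as.numeric(qh$offsets)),
            class = "hull3d")
}

#' @export
print.hull3d <- function(x, ...) {
  cat("hull3d:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' Hull membership test
#' @param hull a [build_hull()] result.
#' @param pts n x 3 matrix of mm coordinates.
#' @param tol containment slack in mm.
#' @return logical vector, `TRUE` for points inside or on the hull.
#' @export
hull_contains <- function(hull, pts, tol = 1e-9) {
  .hull_signed_dist_cpp(as.matrix(pts), hull$normals, hull$offsets) <= tol
}

#' Nearest point on the hull surface
#' @inheritParams hull_contains
#' @return n x 3 matrix of surface points.
#' @export
hull_project <- function(hull, pts) {
  .hull_project_cpp(as.matrix(pts), hull$vertices, hull$faces)
}

#' Hull volume (sum of signed tetrahedra)
#' @param hull a [build_hull()] result.
#' @return volume in mm^3.
#' @export
hull_volume <- function(hull) {
  V <- hull$vertices
  o <- colMeans(V)
  total <- 0
  for (f in seq_len(nrow(hull$faces))) {
    a <- V[hull$faces[f, 1], ] - o
    b <- V[hull$faces[f, 2], ] - o
    cc <- V[hull$faces[f, 3], ] - o
    total <- total + abs(det(rbind(a, b, cc))) / 6
  }
  total
}
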