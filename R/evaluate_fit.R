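#' Evaluate a harmonic fit on a target geometry
#'
#' Computes fitted complex sensitivities for every voxel of the target
#' geometry. Voxels inside the fit's convex hull evaluate the basis at
#' their own mm coordinate; exterior voxels evaluate it at the
#' Euclidean-closest point on the hull surface, so the fit is never
#' extrapolated. Coordinates are normalized with the `(c0, r0)` stored in
#' the fit, which makes re-evaluation on any geometry reproduce the fitted
#' field exactly where grids coincide.
#'
#' @param fit a [fit_variable_exchange()] result (or one read back from a
#'   sidecar with [read_fit_sidecar()]).
#' @param target_geometry a [vol_geometry()].
#' @return list with `sensitivities` (voxel x coil complex matrix on the
#'   target grid, raster order), `inside` (logical, hull membership) and
#'   `geometry`.
#' @export
evaluate_fit <- function(fit, target_geometry) {
  stopifnot(inherits(fit, "harmonic_fit"),
            inherits(target_geometry, "vol_geometry"))
  if (!isTRUE(fit$converged))
    warning("applying a fit that did not converge")
  mm <- voxel_to_mm(target_geometry)
  inside <- hull_contains(fit$hull, mm)
  eval_pts <- mm
  if (any(!inside))
    eval_pts[!inside, ] <- hull_project(fit$hull, mm[!inside, , drop = FALSE])
  coords <- sweep(eval_pts, 2, fit$c0) / fit$r0
  A <- build_basis(coords, fit$order)$A
  list(sensitivities = A %*% fit$coefficients,
       inside = inside,
       geometry = target_geometry)
}
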