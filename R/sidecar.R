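#' Write a harmonic fit to a JSON sidecar
#'
#' Serializes everything needed to re-apply a fit sessions later without
#' the prescan: basis order and column convention, complex coefficients per
#' coil (split into real/imaginary), the `(c0, r0)` coordinate
#' normalization, the convex hull (vertices, faces, normals, offsets), the
#' minimax reference weights and diagnostics, and mask provenance. Numbers
#' are written at full precision.
#'
#' @param fit a [fit_variable_exchange()] result.
#' @param path output `.json` path.
#' @param extra optional named list of additional metadata (e.g. the run
#'   configuration and seeds) stored verbatim.
#' @return `path`, invisibly.
#' @export
write_fit_sidecar <- function(fit, path, extra = list()) {
  stopifnot(inherits(fit, "harmonic_fit"))
  payload <- list(
    format = "coilfit-sidecar-v1",
    order = fit$order,
    n_terms = fit$n_terms,
    column_order = "l ascending; within l, m = -l..l; m<0 are sin terms",
    lm = fit$lm,
    coefficients_real = Re(fit$coefficients),
    coefficients_imag = Im(fit$coefficients),
    c0 = fit$c0, r0 = fit$r0,
    hull = list(vertices = fit$hull$vertices,
                faces = fit$hull$faces,
                normals = fit$hull$normals,
                offsets = fit$hull$offsets),
    reference_weights = list(real = Re(fit$weights_ref),
                             imag = Im(fit$weights_ref)),
    converged = fit$converged,
    iterations = fit$iterations,
    relative_residual = fit$relative_residual,
    residual_history = fit$residual_history,
    n_fit_voxels = length(fit$voxels),
    prescan_matrix_size = fit$geometry$matrix_size,
    prescan_affine = fit$geometry$affine,
    extra = extra
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a harmonic fit back from a JSON sidecar
#'
#' @param path a sidecar written by [write_fit_sidecar()].
#' @return a `harmonic_fit` usable by [evaluate_fit()].
#' @export
read_fit_sidecar <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "coilfit-sidecar-v1"))
    stop(path, " is not a coilfit sidecar")
  as_mat <- function(x) matrix(unlist(x), nrow = NROW(x))
  hull <- structure(list(vertices = as_mat(p$hull$vertices),
                         faces = as_mat(p$hull$faces),
                         normals = as_mat(p$hull$normals),
                         offsets = as.numeric(p$hull$offsets)),
                    class = "hull3d")
  geom <- vol_geometry(p$prescan_matrix_size, as_mat(p$prescan_affine))
  structure(list(
    coefficients = matrix(complex(real = unlist(p$coefficients_real),
                                  imaginary = unlist(p$coefficients_imag)),
                          nrow = p$n_terms),
    order = as.integer(p$order),
    n_terms = as.integer(p$n_terms),
    lm = as_mat(p$lm),
    c0 = as.numeric(p$c0), r0 = as.numeric(p$r0),
    hull = hull,
    converged = isTRUE(p$converged),
    iterations = p$iterations,
    relative_residual = p$relative_residual,
    residual_history = as.numeric(p$residual_history),
    voxels = integer(0),
    weights_ref = complex(real = unlist(p$reference_weights$real),
                          imaginary = unlist(p$reference_weights$imag)),
    geometry = geom,
    extra = p$extra
  ), class = "harmonic_fit")
}
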