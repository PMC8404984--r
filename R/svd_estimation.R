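#' Voxel-wise SVD estimation of relative coil sensitivities
#'
#' At each voxel the coil x image signal matrix `S` is, in the noise-free
#' separable model, rank one: `S = c m^T` with `c` the relative coil
#' sensitivities and `m` the magnetization across images. The best
#' least-squares rank-1 approximation is given by the SVD; the unit-norm
#' first left singular vector estimates the direction of `c`, the first
#' singular value carries the combined magnitude `(c^H c m^H m)^(1/2)`, and
#' the first right singular vector the magnetization series.
#'
#' The SVD phase ambiguity is resolved by assigning the phase of the first
#' image's magnetization to the sensitivities: after the convention the
#' first right-singular entry is real and non-negative, and `c_prime`
#' carries the (arbitrary, B1+/off-resonance contaminated) common phase
#' `phi_m`, which [solve_minimax()] / [remove_common_phase()] later remove.
#'
#' With a single image the decomposition degenerates gracefully: `lambda1`
#' equals the root-sum-of-squares of the coil signals and `lambda2` is 0.
#' All-zero (air) voxels yield zeroed estimates rather than an error; the
#' mask machinery removes them.
#'
#' @param prescan a [coil_image_set()].
#' @return an object of class `sensitivity_estimate`: list with `c_prime`
#'   (voxel x coil complex, unit row norm where `lambda1 > 0`), `m_first`
#'   (complex, real non-negative by convention), `m_series` (voxel x image
#'   complex magnetization series scaled by `lambda1`), `lambda1`, `lambda2`
#'   (non-negative vectors), and `geometry`.
#' @export
voxelwise_svd <- function(prescan) {
  stopifnot(inherits(prescan, "coil_image_set"))
  nv <- n_voxels(prescan$geometry)
  res <- .voxelwise_svd_cpp(prescan$data, nv, prescan$coil_count,
                            prescan$image_count)
  structure(list(c_prime = res$c_prime,
                 m_first = res$m_series[, 1],
                 m_series = res$m_series,
                 lambda1 = as.numeric(res$lambda1),
                 lambda2 = as.numeric(res$lambda2),
                 geometry = prescan$geometry),
            class = "sensitivity_estimate")
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat("sensitivity_estimate:", nrow(x$c_prime), "voxels,",
      ncol(x$c_prime), "coils\n")
  cat("lambda1 range:", paste(signif(range(x$lambda1), 4), collapse = " .. "),
      "\n")
  invisible(x)
}

#' SNR map from the singular-value ratio
#'
#' The ratio of the first and second singular values is an SNR surrogate:
#' object voxels are near rank one (large ratio) while pure-noise voxels
#' have comparable singular values (ratio near 1-2 for typical coil/image
#' counts).
#'
#' @param est a [voxelwise_svd()] estimate.
#' @param eps small positive guard added to `lambda2` before division;
#'   default is machine-epsilon scaled by the largest `lambda1`.
#' @return non-negative numeric vector, one value per voxel.
#' @export
snr_map <- function(est, eps = .Machine$double.eps * max(est$lambda1, 1)) {
  stopifnot(inherits(est, "sensitivity_estimate"), eps > 0)
  est$lambda1 / (est$lambda2 + eps)
}

#' Threshold an SNR map into a mask
#'
#' @param snr non-negative numeric vector from [snr_map()].
#' @param threshold positive threshold; voxels with `snr >= threshold` are
#'   kept.
#' @param provenance label recorded with the mask (`"minimax"` or `"fit"`).
#' @return an object of class `snr_mask`: logical vector plus the threshold
#'   and provenance used.
#' @export
snr_threshold_mask <- function(snr, threshold,
                               provenance = c("fit", "minimax")) {
  provenance <- match.arg(provenance)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive")
  mask <- is.finite(snr) & snr >= threshold
  if (!any(mask))
    stop("SNR threshold ", threshold,
         " leaves an empty mask (max SNR = ", signif(max(snr), 4),
         "); nothing to fit")
  structure(list(mask = mask, threshold = threshold,
                 provenance = provenance, n = sum(mask)),
            class = "snr_mask")
}

#' @export
print.snr_mask <- function(x, ...) {
  cat("snr_mask (", x$provenance, "): ", x$n, " voxels at threshold ",
      x$threshold, "\n", sep = "")
  invisible(x)
}
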