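#' @name combiners
#' @title Coil combination methods
#'
#' @description
#' Phase-sensitive combiners producing one complex volume per input
#' image/volume. `combine_fitted()` is the method of interest: each voxel's
#' coil vector is projected onto the normalized conjugate of the fitted
#' sensitivities, `v = c_hat^H s / ||c_hat||` — a matched filter that aligns
#' phases before summation and attains the voxel-wise SVD magnitude when
#' the sensitivities are exact. The remaining combiners are the comparison
#' baselines: naive complex sum, the virtual-reference-coil method, and the
#' voxel-wise SVD combination that serves as the quality-ratio reference.
#'
#' All combiners are global-phase equivariant (multiplying every coil by
#' `exp(1i*gamma)` multiplies the output by the same factor) and operate
#' independently on each volume of a series.
NULL

combined_volume <- function(values, geometry, method, provenance = list()) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  structure(list(values = values, geometry = geometry, method = method,
                 provenance = provenance),
            class = "combined_volume")
}

#' @export
print.combined_volume <- function(x, ...) {
  cat("combined_volume [", x$method, "]: ",
      paste(x$geometry$matrix_size, collapse = " x "), " voxels, ",
      ncol(x$values), " volume(s)\n", sep = "")
  invisible(x)
}

#' @rdname combiners
#' @param target a [coil_image_set()] to combine.
#' @param fitted voxel x coil complex matrix of sensitivities evaluated on
#'   the target geometry (`evaluate_fit(...)$sensitivities`), or an
#'   `evaluate_fit()` result.
#' @param eps relative magnitude floor: at each voxel, coils whose fitted
#'   magnitude is below `eps * max_i |c_hat_i|` are dropped from the sum.
#' @return a `combined_volume`: complex voxel x volume matrix plus
#'   geometry and method label.
#' @export
combine_fitted <- function(target, fitted, eps = 1e-6) {
  stopifnot(inherits(target, "coil_image_set"))
  if (is.list(fitted) && !is.null(fitted$sensitivities))
    fitted <- fitted$sensitivities
  nv <- n_voxels(target$geometry)
  if (nrow(fitted) != nv || ncol(fitted) != target$coil_count)
    stop("fitted sensitivities do not match the target geometry/coil count")
  mag <- Mod(fitted)
  drop <- mag < eps * apply(mag, 1, max)
  fitted[drop] <- 0
  nrm <- sqrt(rowSums(Mod(fitted)^2))
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  out <- matrix(0i, nv, target$image_count)
  for (j in seq_len(target$image_count))
    out[, j] <- scale * rowSums(Conj(fitted) * target$data[, , j])
  combined_volume(out, target$geometry, "fitted",
                  list(eps = eps, dropped = sum(drop)))
}

#' @rdname combiners
#' @export
combine_complex_sum <- function(target) {
  stopifnot(inherits(target, "coil_image_set"))
  out <- apply(target$data, 3, rowSums)
  combined_volume(out, target$geometry, "complex_sum")
}

#' @rdname combiners
#' @param smoothing_fwhm full width at half maximum, in mm, of the 3-D
#'   Gaussian used to smooth the per-coil phase offsets (smoothing acts on
#'   the complex exponentials of the offsets to avoid wrap artifacts).
#' @details
#' `combine_vrc()` picks the reference voxel as the one with the largest
#' minimum magnitude across coils (ties broken by lowest raster index) in
#' the first volume, subtracts that voxel's per-coil phases, sums the
#' phase-adjusted coils into a virtual reference, smooths each coil's phase
#' offset to the reference, and aligns before complex summation. Offsets
#' from the first volume are applied to every volume. A poorly supported
#' reference voxel reproduces the known failure mode: a reference with
#' nulls that leaks singularities into the output.
#' @export
combine_vrc <- function(target, smoothing_fwhm = 10) {
  stopifnot(inherits(target, "coil_image_set"))
  s1 <- target$data[, , 1, drop = FALSE]
  dim(s1) <- dim(target$data)[1:2]
  mag <- Mod(s1)
  minmag <- apply(mag, 1, min)
  ref_voxel <- which.max(minmag)
  theta <- Arg(s1[ref_voxel, ])
  refcoil <- as.vector(s1 %*% exp(-1i * theta))  # virtual reference
  # per-coil offsets to the reference, smoothed as complex exponentials
  offsets <- matrix(0, nrow(s1), ncol(s1))
  for (i in seq_len(ncol(s1))) {
    z <- s1[, i] * Conj(refcoil)
    mz <- Mod(z)
    z <- ifelse(mz > 0, z / mz, 0i)
    zs <- gaussian_smooth3d(z, target$geometry, smoothing_fwhm)
    offsets[, i] <- Arg(zs)
  }
  out <- matrix(0i, nrow(s1), target$image_count)
  for (j in seq_len(target$image_count))
    out[, j] <- rowSums(target$data[, , j] * exp(-1i * offsets))
  combined_volume(out, target$geometry, "vrc",
                  list(ref_voxel = ref_voxel, smoothing_fwhm = smoothing_fwhm))
}

#' @rdname combiners
#' @param target_multivolume a multi-volume [coil_image_set()].
#' @details
#' `combine_vsvd()` performs the voxel-wise SVD across volumes and returns
#' `lambda1` times the magnetization series with the first volume's phase
#' set to zero, making it a measure of relative phase; it is the reference
#' (`S_VSVD`) of the quality-ratio and phase-noise metrics.
#' @export
combine_vsvd <- function(target_multivolume) {
  est <- voxelwise_svd(target_multivolume)
  combined_volume(est$m_series, target_multivolume$geometry, "vsvd")
}

#' Separable 3-D Gaussian smoothing on the voxel grid
#'
#' Kernel widths are specified in mm and converted per axis using the
#' affine's voxel spacing; borders are renormalized (kernel mass inside the
#' volume sums to 1). Complex input is smoothed component-wise.
#'
#' @param values vector over voxels (raster order) or 3-D array.
#' @param geometry the [vol_geometry()].
#' @param fwhm_mm full width at half maximum in mm.
#' @return smoothed values, same shape as the input.
#' @export
gaussian_smooth3d <- function(values, geometry, fwhm_mm) {
  d <- geometry$matrix_size
  x <- array(values, dim = d)
  spacing <- sqrt(colSums(geometry$affine[1:3, 1:3]^2))
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / spacing
  for (ax in 1:3) {
    sg <- sigma_vox[ax]
    if (sg <= 0) next
    half <- max(1L, ceiling(3 * sg))
    kern <- stats::dnorm(-half:half, sd = sg)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- kern[ok] / sum(kern[ok])
    }
    x <- apply_along_axis(x, ax, K)
  }
  if (is.null(dim(values))) as.vector(x) else x
}

# multiply matrix K (n x n) along axis `ax` of 3-D array x
apply_along_axis <- function(x, ax, K) {
  d <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  dim(xp) <- c(d[ax], prod(d[-ax]))
  xp <- K %*% xp
  dim(xp) <- d[perm]
  aperm(xp, order(perm))
}
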