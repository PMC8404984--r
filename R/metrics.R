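#' Quality ratio of a combination against the voxel-wise SVD reference
#'
#' `Q = |S_method| / |S_reference|` voxel-wise over an evaluation mask.
#' Voxels whose reference magnitude is below `threshold_frac` (default 3%)
#' of the masked median reference magnitude are excluded to avoid outliers
#' where signal is naturally too low to compare methods. The report carries
#' the Q map, its mean and standard deviation over the evaluation mask, and
#' the coefficient of variation `CV = sigma/mu * 100`. Q depends on
#' magnitudes only, so it is invariant to any voxel-wise phase change of
#' either input.
#'
#' @param method,reference `combined_volume` objects (or voxel x volume
#'   complex matrices) on the same geometry, with matching volume counts.
#' @param brain_mask logical vector over voxels (e.g. the phantom support
#'   or a user-supplied brain mask, already eroded as desired).
#' @param threshold_frac exclusion fraction of the masked median reference
#'   magnitude.
#' @return object of class `quality_report`: `q_map` (voxel x volume, NA
#'   outside the evaluation mask), `mean`, `sd`, `cv`, `n_excluded`,
#'   `n_eval`.
#' @export
quality_ratio <- function(method, reference, brain_mask,
                          threshold_frac = 0.03) {
  m <- if (inherits(method, "combined_volume")) method$values else method
  r <- if (inherits(reference, "combined_volume")) reference$values else
    reference
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  if (is.null(dim(r))) r <- matrix(r, ncol = 1)
  if (!all(dim(m) == dim(r)))
    stop("method and reference have different shapes")
  if (length(brain_mask) != nrow(r))
    stop("brain mask does not match the volumes")
  rmag <- Mod(r)
  mmag <- Mod(m)
  inmask <- matrix(brain_mask, nrow(r), ncol(r))
  med <- stats::median(rmag[inmask])
  if (!is.finite(med) || med <= 0) stop("evaluation mask is empty")
  eval_mask <- inmask & rmag >= threshold_frac * med
  n_excluded <- sum(inmask) - sum(eval_mask)
  if (!any(eval_mask)) stop("evaluation mask is empty after 3% exclusion")
  q <- mmag / rmag
  q[!eval_mask] <- NA_real_
  vals <- q[eval_mask]
  mu <- mean(vals)
  sd_ <- stats::sd(vals)
  if (length(vals) == 1L) sd_ <- 0
  structure(list(q_map = q, mean = mu, sd = sd_,
                 cv = if (mu > 0) sd_ / mu * 100 else NA_real_,
                 n_excluded = n_excluded, n_eval = sum(eval_mask),
                 threshold_frac = threshold_frac),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report: mean Q = %.4f, sd = %.4f, CV = %.2f%% (n = %d, excluded = %d)\n",
              x$mean, x$sd, x$cv, x$n_eval, x$n_excluded))
  invisible(x)
}

#' Count phase singularities by plaquette residues
#'
#' A phase singularity is a point where the combined magnitude vanishes and
#' the phase winds by +/- 2*pi around it. For every axis-aligned 2x2
#' plaquette in each of the three slice orientations, the four wrapped
#' phase differences around the loop are summed; residues are plaquettes
#' whose winding is +/- 2*pi. Only plaquettes with all four corners inside
#' the mask are counted. Smooth (residue-free) phase fields, including
#' arbitrary linear ramps, count zero.
#'
#' @param phase 3-D array of phase values in radians (or a vector over
#'   voxels together with `geometry`).
#' @param mask logical array/vector of the volume of interest (default all).
#' @param geometry optional [vol_geometry()] when `phase` is a vector.
#' @return list with `total`, `by_orientation` (counts for plaquettes in
#'   the xy, xz and yz planes) and `locations` (matrix of plaquette corner
#'   indices and orientation).
#' @export
count_singularities <- function(phase, mask = NULL, geometry = NULL) {
  if (is.null(dim(phase)) || length(dim(phase)) != 3L) {
    if (is.null(geometry)) stop("need 3-D phase or a geometry")
    phase <- array(phase, dim = geometry$matrix_size)
  }
  d <- dim(phase)
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  if (is.null(dim(mask))) mask <- array(mask, dim = d)

  planes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  names(planes) <- c("xy", "xz", "yz")
  counts <- integer(3)
  locs <- list()
  for (p in 1:3) {
    ax <- planes[[p]]
    res <- plaquette_residues(phase, mask, ax)
    counts[p] <- nrow(res)
    if (nrow(res) > 0)
      locs[[names(planes)[p]]] <- cbind(res, orientation = p)
  }
  names(counts) <- names(planes)
  list(total = sum(counts), by_orientation = counts,
       locations = if (length(locs)) do.call(rbind, locs) else NULL)
}

# winding of 2x2 plaquettes in the plane of axes `ax` (other axis fixed)
plaquette_residues <- function(phase, mask, ax) {
  d <- dim(phase)
  shift <- function(arr, axis) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[axis]] <- seq_len(d[axis] - 1) + 1
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  crop <- function(arr, axis) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[axis]] <- seq_len(d[axis] - 1)
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  a1 <- ax[1]; a2 <- ax[2]
  p00 <- crop(crop(phase, a1), a2)
  p10 <- crop(shift(phase, a1), a2)
  p11 <- shift(shift(phase, a1), a2)
  p01 <- shift(crop(phase, a1), a2)
  wind <- wrap_phase(p10 - p00) + wrap_phase(p11 - p10) +
    wrap_phase(p01 - p11) + wrap_phase(p00 - p01)
  m00 <- crop(crop(mask, a1), a2)
  m10 <- crop(shift(mask, a1), a2)
  m11 <- shift(shift(mask, a1), a2)
  m01 <- shift(crop(mask, a1), a2)
  hit <- which(abs(wind) > pi & m00 & m10 & m11 & m01, arr.ind = TRUE)
  hit
}

#' Temporal phase-noise ratio between two combined series
#'
#' For each series the first volume's phase is removed, phases are
#' unwrapped through time (multiples of 2*pi added so successive
#' differences lie in `(-pi, pi]`), a per-voxel linear trend is removed,
#' and the temporal standard deviation taken. The report is the voxel-wise
#' ratio `sigma_method / sigma_reference`, summarized over the brain mask
#' after the same 3%-of-median magnitude exclusion as the quality ratio
#' (using the reference's mean magnitude). Identical series give a ratio
#' of exactly 1; static per-voxel phase offsets and linear temporal drifts
#' do not affect the ratio.
#'
#' @param method_series,reference_series `combined_volume` objects or
#'   voxel x time complex matrices with at least 3 time points.
#' @param brain_mask logical vector over voxels.
#' @param threshold_frac magnitude exclusion fraction.
#' @return object of class `phase_noise_report`: `ratio_map`, `sd_method`,
#'   `sd_reference`, `mean_ratio`, `n_eval`.
#' @export
phase_noise_ratio <- function(method_series, reference_series, brain_mask,
                              threshold_frac = 0.03) {
  m <- if (inherits(method_series, "combined_volume")) method_series$values
       else method_series
  r <- if (inherits(reference_series, "combined_volume"))
    reference_series$values else reference_series
  if (ncol(m) < 3) stop("need at least 3 time points")
  if (!all(dim(m) == dim(r))) stop("series have different shapes")
  sd_m <- temporal_phase_sd(m)
  sd_r <- temporal_phase_sd(r)
  ratio <- ifelse(sd_r > 0, sd_m / sd_r, NA_real_)
  rmag <- rowMeans(Mod(r))
  med <- stats::median(rmag[brain_mask])
  eval_mask <- brain_mask & rmag >= threshold_frac * med & is.finite(ratio)
  if (!any(eval_mask)) stop("evaluation mask is empty")
  structure(list(ratio_map = ratio, sd_method = sd_m, sd_reference = sd_r,
                 mean_ratio = mean(ratio[eval_mask]),
                 n_eval = sum(eval_mask)),
            class = "phase_noise_report")
}

#' @export
print.phase_noise_report <- function(x, ...) {
  cat(sprintf("phase_noise_report: mean ratio = %.4f (n = %d)\n",
              x$mean_ratio, x$n_eval))
  invisible(x)
}

# per-voxel sd of the temporally-unwrapped, linearly-detrended phase
temporal_phase_sd <- function(series) {
  ph <- Arg(series * Conj(series[, 1]))  # remove volume-1 phase
  dd <- wrap_phase(ph[, -1, drop = FALSE] - ph[, -ncol(ph), drop = FALSE])
  unwrapped <- cbind(ph[, 1], ph[, 1] + t(apply(dd, 1, cumsum)))
  t <- seq_len(ncol(unwrapped))
  tc <- t - mean(t)
  beta <- (unwrapped %*% tc) / sum(tc^2)
  detr <- unwrapped - beta %*% t(tc)
  detr <- detr - rowMeans(detr)
  sqrt(rowSums(detr^2) / (ncol(detr) - 1))
}

#' Evaluation mask from a magnitude image
#'
#' Thresholds a (e.g. sum-of-squares) magnitude volume at a fraction of the
#' median over its nonzero support and erodes the result with a
#' 6-connected structuring element the requested number of times.
#'
#' @param magnitude non-negative vector over voxels or 3-D array.
#' @param geometry the [vol_geometry()] (needed when `magnitude` is a
#'   vector).
#' @param threshold_frac fraction of the in-support median.
#' @param erosions number of 6-connected erosions.
#' @return logical vector over voxels in raster order.
#' @export
make_eval_mask <- function(magnitude, geometry = NULL, threshold_frac = 0.03,
                           erosions = 1) {
  if (is.null(dim(magnitude)) || length(dim(magnitude)) != 3L) {
    if (is.null(geometry)) stop("need 3-D magnitude or a geometry")
    magnitude <- array(magnitude, dim = geometry$matrix_size)
  }
  if (any(magnitude < 0)) stop("magnitude must be non-negative")
  support <- magnitude > 0
  if (!any(support)) stop("magnitude volume is identically zero")
  med <- stats::median(magnitude[support])
  mask <- magnitude >= threshold_frac * med
  for (i in seq_len(erosions)) mask <- erode6(mask)
  if (!any(mask)) stop("evaluation mask empty after erosion")
  as.vector(mask)
}

# one 6-connected binary erosion (faces-only neighbourhood), edge voxels
# treated as background neighbours
erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  pad_shift <- function(arr, axis, by) {
    res <- array(FALSE, dim = d)
    idx_src <- rep(list(quote(expr = )), 3)
    idx_dst <- rep(list(quote(expr = )), 3)
    n <- d[axis]
    if (by == 1) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    res_idx <- c(list(res), idx_dst, list(do.call(`[`, c(list(arr), idx_src, list(drop = FALSE)))))
    do.call(`[<-`, res_idx)
  }
  for (axis in 1:3) for (by in c(1, -1))
    out <- out & pad_shift(mask, axis, by)
  out
}
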