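#' Ground-truth coil sensitivities for synthetic phantoms
#'
#' Two generative models are available:
#'
#' * `"harmonic"` draws complex coefficients for the real solid-harmonic
#'   basis up to the given order (i.i.d. standard complex Gaussian, seeded)
#'   and evaluates them on the grid. Independent coefficients across many
#'   coils give strongly varying per-coil phases, which reproduces the
#'   destructive interference that makes naive complex-sum combination fail
#'   at ultra-high field. These fields lie exactly in the span of any fit
#'   basis of at least the generating order.
#' * `"loops"` places circular "current loop" surrogates around the object
#'   and evaluates a smooth inverse-distance magnitude falloff with a
#'   distance-dependent phase per coil — deliberately outside the harmonic
#'   span, for stress tests.
#'
#' Sensitivities are defined as fields over physical mm coordinates
#' (coefficients plus a `(c0, r0)` normalization), so the same truth can be
#' evaluated on any geometry via [eval_sensitivities()] — this is what lets
#' prescan-estimated fits be validated against target-grid ground truth.
#'
#' @param geometry native [vol_geometry()] of the phantom.
#' @param n_coils number of receive coils.
#' @param model `"harmonic"` or `"loops"`.
#' @param order harmonic order of the truth (harmonic model).
#' @param loop_radius radial distance of the loop centres from the volume
#'   centre, in mm (loops model; default 1.15 * r0).
#' @param sum_vortex_mm optional `(x0, y0)` in mm (harmonic model only):
#'   the coil coefficients are redistributed so that the coil-sum field is
#'   exactly `scale * ((x - x0) + 1i (y - y0))` in normalized coordinates —
#'   a destructive-interference construction guaranteeing that the naive
#'   complex-sum combination has a null line of winding +1 through
#'   `(x0, y0)`, while every individual coil stays a smooth in-span
#'   harmonic field.
#' @param sum_vortex_scale amplitude of the constructed sum field
#'   (default `n_coils`, comparable to a coherent coil sum).
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return object of class `ground_truth_sensitivities` with `values`
#'   (voxel x coil complex on `geometry`), the model descriptor, and seed.
#' @export
simulate_sensitivities <- function(geometry, n_coils = 32,
                                   model = c("harmonic", "loops"),
                                   order = 3, loop_radius = NULL,
                                   sum_vortex_mm = NULL,
                                   sum_vortex_scale = n_coils, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_coils >= 1)
  if (model == "harmonic" && order < 0) stop("order must be >= 0")
  mm <- voxel_to_mm(geometry)
  c0 <- colMeans(mm)
  r0 <- max(sqrt(rowSums(sweep(mm, 2, c0)^2)))
  out <- list(model = model, n_coils = n_coils, seed = seed,
              c0 = c0, r0 = r0, geometry = geometry)
  if (model == "harmonic") {
    n_terms <- (order + 1)^2
    coeffs <- with_seed(seed, matrix(
      complex(real = stats::rnorm(n_terms * n_coils),
              imaginary = stats::rnorm(n_terms * n_coils)),
      n_terms, n_coils))
    if (!is.null(sum_vortex_mm)) {
      if (order < 1) stop("sum_vortex_mm needs order >= 1")
      # columns 1..4 are (0,0), (1,-1)=sin~ -y, (1,0)=z, (1,1)=cos~ -x
      xv <- (sum_vortex_mm[1] - c0[1]) / r0
      yv <- (sum_vortex_mm[2] - c0[2]) / r0
      Xv <- rep(0i, n_terms)
      Xv[1] <- -(xv + 1i * yv)
      Xv[2] <- -1i
      Xv[4] <- -1 + 0i
      Xv <- Xv * sum_vortex_scale
      coeffs <- coeffs - (rowSums(coeffs) - Xv) / n_coils
    }
    out$order <- as.integer(order)
    out$coefficients <- coeffs
  } else {
    if (is.null(loop_radius)) loop_radius <- 1.15 * r0
    ang <- with_seed(seed, stats::runif(1, 0, 2 * pi)) +
      2 * pi * (seq_len(n_coils) - 1) / n_coils
    zpos <- rep(c(-0.3, 0.3) * r0, length.out = n_coils)
    out$loop_centers <- cbind(c0[1] + loop_radius * cos(ang),
                              c0[2] + loop_radius * sin(ang),
                              c0[3] + zpos)
    out$loop_radius <- loop_radius
    out$phase_offsets <- with_seed(seed + 1,
                                   stats::runif(n_coils, -pi, pi))
  }
  out$values <- eval_sensitivities(out, geometry)
  class(out) <- "ground_truth_sensitivities"
  out
}

#' Evaluate ground-truth sensitivities on an arbitrary geometry
#'
#' @param truth a [simulate_sensitivities()] result.
#' @param geometry the [vol_geometry()] to evaluate on.
#' @param shift_mm optional length-3 rigid shift (mm) applied to the truth
#'   field relative to the grid — used to emulate subject motion between
#'   prescan and target.
#' @return voxel x coil complex matrix.
#' @export
eval_sensitivities <- function(truth, geometry, shift_mm = c(0, 0, 0)) {
  mm <- sweep(voxel_to_mm(geometry), 2, as.numeric(shift_mm))
  if (truth$model == "harmonic") {
    coords <- sweep(mm, 2, truth$c0) / truth$r0
    A <- build_basis(coords, truth$order)$A
    A %*% truth$coefficients
  } else {
    r0 <- truth$r0
    vals <- matrix(0i, nrow(mm), truth$n_coils)
    for (i in seq_len(truth$n_coils)) {
      dist <- sqrt(rowSums(sweep(mm, 2, truth$loop_centers[i, ])^2))
      vals[, i] <- (r0 / (dist + 0.25 * r0)) *
        exp(1i * (2 * dist / r0 + truth$phase_offsets[i]))
    }
    vals
  }
}

#' @export
print.ground_truth_sensitivities <- function(x, ...) {
  cat("ground_truth_sensitivities:", x$n_coils, "coils, model", x$model,
      if (x$model == "harmonic") paste("order", x$order), "\n")
  invisible(x)
}

#' Phantom scene: object support, magnetization, B1+ phase, noise level
#'
#' The scene is parameterized in physical mm units so it can be rendered on
#' any geometry. The object is an ellipsoid inscribed in the field of view;
#' the transmit (B1+) phase is a smooth quadratic polynomial plus optional
#' vortex terms (atan2-style winding around lines parallel to z), which the
#' magnetization phase shares across all coils and images — the structure
#' the common-phase removal step must cope with. Prescan images carry large
#' contrast variation (an AFI-like first image of unit contrast plus
#' Fourier-encoded-B1+-like images with seeded complex scalars, magnitude
#' in \[0.2, 1\] and phase in (-pi, pi]); target volumes carry unit
#' magnitude with a seeded global phase per volume. The complex noise
#' standard deviation is set from the requested SNR as
#' `mean in-object |signal| / snr`.
#'
#' @param geometry native [vol_geometry()] (used for defaults only).
#' @param n_images number of prescan images (default 9: AFI + 8 B1+).
#' @param snr target signal-to-noise ratio (mean in-object coil-image
#'   magnitude over complex noise sd).
#' @param semi_axes_mm ellipsoid semi-axes; default 0.42 of the FOV extent
#'   per axis.
#' @param vortices `NULL`, or a matrix with rows `(x0_mm, y0_mm, charge)`
#'   of vortex line cores (lines parallel to z).
#' @param b1_amp amplitude scale (radians) of the smooth quadratic B1+
#'   phase component.
#' @param seed integer seed.
#' @return object of class `phantom_scene`.
#' @export
phantom_scene <- function(geometry, n_images = 9, snr = 50,
                          semi_axes_mm = NULL, vortices = NULL,
                          b1_amp = 2, seed = 1) {
  mm <- voxel_to_mm(geometry)
  c0 <- colMeans(mm)
  fov <- apply(mm, 2, function(v) diff(range(v)))
  if (is.null(semi_axes_mm)) semi_axes_mm <- 0.42 * fov
  contrasts <- with_seed(seed, {
    mags <- c(1, stats::runif(max(n_images - 1, 0), 0.2, 1))
    phs <- c(0, stats::runif(max(n_images - 1, 0), -pi, pi))
    mags * exp(1i * phs)
  })
  poly <- with_seed(seed + 1, stats::rnorm(9, sd = b1_amp / 3))
  structure(list(center = c0, semi_axes = semi_axes_mm,
                 n_images = n_images, contrasts = contrasts,
                 b1_poly = poly, b1_amp = b1_amp,
                 vortices = vortices, snr = snr, seed = seed),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat("phantom_scene:", x$n_images, "images, SNR", x$snr, ",",
      if (is.null(x$vortices)) 0 else nrow(x$vortices), "B1+ vortices\n")
  invisible(x)
}

#' Render scene fields (support and B1+ phase) on a geometry
#' @param scene a [phantom_scene()].
#' @param geometry a [vol_geometry()].
#' @return list with `support` (logical vector) and `b1_phase` (radians).
#' @export
scene_fields <- function(scene, geometry) {
  mm <- voxel_to_mm(geometry)
  u <- sweep(mm, 2, scene$center)
  un <- sweep(u, 2, scene$semi_axes, "/")
  support <- rowSums(un^2) <= 1
  p <- scene$b1_poly
  b1 <- p[1] + p[2] * un[, 1] + p[3] * un[, 2] + p[4] * un[, 3] +
    p[5] * un[, 1] * un[, 2] + p[6] * un[, 1] * un[, 3] +
    p[7] * un[, 2] * un[, 3] + p[8] * (un[, 1]^2 - un[, 3]^2) +
    p[9] * (un[, 2]^2 - un[, 3]^2)
  if (!is.null(scene$vortices))
    for (i in seq_len(nrow(scene$vortices))) {
      v <- scene$vortices[i, ]
      b1 <- b1 + v[3] * atan2(mm[, 2] - v[2], mm[, 1] - v[1])
    }
  list(support = support, b1_phase = b1)
}

#' Simulate a multi-image prescan
#'
#' Renders the separable signal model `s_ij = c_i * m_j` per voxel: the
#' magnetization `m_j` is the object support times the per-image contrast
#' scalar times the common B1+ phase field, and complex Gaussian noise is
#' added at the scene's SNR. Noise-free data are exactly rank one per
#' voxel.
#'
#' @param truth a [simulate_sensitivities()] result.
#' @param scene a [phantom_scene()].
#' @param n_images number of images (defaults to the scene's; must not
#'   exceed it).
#' @param seed noise seed.
#' @param geometry geometry to render on (defaults to the truth's native
#'   geometry).
#' @return a [coil_image_set()].
#' @export
simulate_prescan <- function(truth, scene, n_images = scene$n_images,
                             seed = 1, geometry = truth$geometry) {
  stopifnot(inherits(truth, "ground_truth_sensitivities"),
            inherits(scene, "phantom_scene"))
  if (n_images > scene$n_images)
    stop("scene provides only ", scene$n_images, " image contrasts")
  sens <- if (identical(geometry, truth$geometry)) truth$values else
    eval_sensitivities(truth, geometry)
  fields <- scene_fields(scene, geometry)
  m0 <- as.numeric(fields$support) * exp(1i * fields$b1_phase)
  nv <- n_voxels(geometry)
  n_coils <- ncol(sens)
  data <- array(0i, dim = c(nv, n_coils, n_images))
  for (j in seq_len(n_images))
    data[, , j] <- sens * (m0 * scene$contrasts[j])
  sd_noise <- noise_sd_for(data, fields$support, scene$snr)
  if (sd_noise > 0)
    data <- data + with_seed(seed,
      array(complex_noise(length(data), sd_noise), dim = dim(data)))
  coil_image_set(data, geometry)
}

#' Simulate a target acquisition sharing the prescan's ground truth
#'
#' Renders the same physical sensitivity fields on a (typically finer)
#' target geometry with unit-magnitude magnetization per volume, a seeded
#' global phase per volume, the shared B1+ phase field, and complex
#' Gaussian noise at the scene's SNR. An optional rigid `shift_mm` of the
#' truth emulates subject motion between prescan and target.
#'
#' @inheritParams simulate_prescan
#' @param n_volumes number of target volumes.
#' @param geometry target [vol_geometry()]; must overlap the object.
#' @param shift_mm rigid shift of the sensitivity fields in mm.
#' @return a [coil_image_set()].
#' @export
simulate_target <- function(truth, scene, n_volumes = 5, seed = 2,
                            geometry = NULL, shift_mm = c(0, 0, 0)) {
  stopifnot(inherits(truth, "ground_truth_sensitivities"),
            inherits(scene, "phantom_scene"))
  if (is.null(geometry)) geometry <- truth$geometry
  fields <- scene_fields(scene, geometry)
  if (!any(fields$support))
    stop("target geometry does not overlap the object support")
  sens <- eval_sensitivities(truth, geometry, shift_mm = shift_mm)
  vol_phase <- with_seed(seed, stats::runif(n_volumes, -pi, pi))
  m0 <- as.numeric(fields$support) * exp(1i * fields$b1_phase)
  nv <- n_voxels(geometry)
  data <- array(0i, dim = c(nv, ncol(sens), n_volumes))
  for (j in seq_len(n_volumes))
    data[, , j] <- sens * (m0 * exp(1i * vol_phase[j]))
  sd_noise <- noise_sd_for(data, fields$support, scene$snr)
  if (sd_noise > 0)
    data <- data + with_seed(seed + 1,
      array(complex_noise(length(data), sd_noise), dim = dim(data)))
  coil_image_set(data, geometry)
}

noise_sd_for <- function(data, support, snr) {
  if (is.infinite(snr)) return(0)
  mean(Mod(data[support, , ])) / snr
}

#' The standard desk-scale phantom
#'
#' The package's reference study conditions: 32 coils with order-3 harmonic
#' ground-truth sensitivities, an ellipsoid object, a 9-image 32x32x32
#' prescan at 8 mm isotropic resolution and SNR 50, and a 5-volume 64^3
#' target over the same 256 mm field of view (4 mm isotropic) sharing the
#' same physical sensitivity fields.
#'
#' @param seed master seed; sub-seeds for truth, scene, prescan and target
#'   noise are derived from it.
#' @param n_coils,order,snr,n_images,n_volumes scene overrides.
#' @param prescan_n,target_n grid sizes per axis.
#' @param vortices optional vortex matrix passed to [phantom_scene()].
#' @param sum_vortex_mm optional destructive-interference construction
#'   passed to [simulate_sensitivities()].
#' @param target_shift_mm rigid truth shift for the target (motion
#'   emulation).
#' @return list with `truth`, `scene`, `prescan`, `target`,
#'   `prescan_geometry`, `target_geometry`, `support` (target-grid logical
#'   support).
#' @export
standard_phantom <- function(seed = 1, n_coils = 32, order = 3, snr = 50,
                             n_images = 9, n_volumes = 5,
                             prescan_n = 32, target_n = 64,
                             vortices = NULL, sum_vortex_mm = NULL,
                             target_shift_mm = c(0, 0, 0)) {
  fov <- 256
  pg <- centered_geometry(prescan_n, fov / prescan_n)
  tg <- centered_geometry(target_n, fov / target_n)
  truth <- simulate_sensitivities(pg, n_coils = n_coils, model = "harmonic",
                                  order = order,
                                  sum_vortex_mm = sum_vortex_mm, seed = seed)
  scene <- phantom_scene(pg, n_images = n_images, snr = snr,
                         vortices = vortices, seed = seed + 1000)
  prescan <- simulate_prescan(truth, scene, seed = seed + 2000)
  target <- simulate_target(truth, scene, n_volumes = n_volumes,
                            seed = seed + 3000, geometry = tg,
                            shift_mm = target_shift_mm)
  list(truth = truth, scene = scene, prescan = prescan, target = target,
       prescan_geometry = pg, target_geometry = tg,
       support = scene_fields(scene, tg)$support)
}
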