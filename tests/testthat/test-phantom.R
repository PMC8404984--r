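test_that("sensitivity generators are deterministic and span-consistent", {
  g <- tiny_geometry(10)
  a <- simulate_sensitivities(g, n_coils = 3, order = 2, seed = 42)
  b <- simulate_sensitivities(g, n_coils = 3, order = 2, seed = 42)
  expect_identical(a$values, b$values)

  # order 0, one coil: spatially constant
  con <- simulate_sensitivities(g, n_coils = 1, order = 0, seed = 1)
  expect_lt(max(Mod(con$values - con$values[1])), 1e-12)

  # order-L harmonic field projected onto the order-L basis is exact
  tr <- simulate_sensitivities(g, n_coils = 4, order = 3, seed = 7)
  co <- voxel_coordinates(g, c0 = tr$c0, r0 = tr$r0)
  A <- build_basis(co, 3)$A
  ls_complex <- function(A, b) qr.solve(A, Re(b)) + 1i * qr.solve(A, Im(b))
  proj <- A %*% ls_complex(A, tr$values)
  expect_lt(max(Mod(proj - tr$values)) / max(Mod(tr$values)), 1e-10)

  # loops model is smooth, nonzero, and deterministic
  lp <- simulate_sensitivities(g, n_coils = 5, model = "loops", seed = 3)
  expect_true(all(Mod(lp$values) > 0))
  expect_identical(lp$values,
                   simulate_sensitivities(g, n_coils = 5, model = "loops",
                                          seed = 3)$values)
})

test_that("noise-free prescans are exactly rank one per voxel", {
  ph <- small_phantom(seed = 2, n = 10, n_coils = 5, snr = Inf)
  est <- voxelwise_svd(ph$prescan)
  sup <- scene_fields(ph$scene, ph$prescan_geometry)$support
  expect_true(all(est$lambda2[sup] < 1e-10 * est$lambda1[sup]))
  # truth sensitivities are image-independent; magnetization coil-independent
  dat <- ph$prescan$data
  v <- which(sup)[1]
  S <- dat[v, , ]
  minor <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  expect_lt(Mod(minor), 1e-12 * max(Mod(S))^2)  # 2x2 minors vanish, rank 1
})

test_that("prescan noise level matches the scene SNR", {
  g0 <- centered_geometry(22, 256 / 22)
  truth <- simulate_sensitivities(g0, n_coils = 8, order = 2, seed = 9)
  scene <- phantom_scene(g0, n_images = 4, snr = 20, seed = 10)
  clean <- simulate_prescan(truth, phantom_scene(g0, n_images = 4, snr = Inf,
                                                 seed = 10), seed = 1)
  noisy <- simulate_prescan(truth, scene, seed = 1)
  sup <- scene_fields(scene, g0)$support
  sigma_expect <- mean(Mod(clean$data[sup, , ])) / 20
  resid <- noisy$data - clean$data
  sigma_obs <- sqrt(mean(Mod(resid)^2))  # ~4e4 complex samples
  expect_lt(abs(sigma_obs - sigma_expect) / sigma_expect, 0.05)
})

test_that("B1+ vortices contaminate every coil image but not the truth", {
  g <- centered_geometry(24, 256 / 24)
  truth <- simulate_sensitivities(g, n_coils = 3, order = 1, seed = 5)
  vort <- matrix(c(0, 0, 1), nrow = 1)  # core through the object centre
  scene <- phantom_scene(g, n_images = 2, snr = Inf, vortices = vort,
                         seed = 6)
  pre <- simulate_prescan(truth, scene, seed = 1)
  sup <- array(scene_fields(scene, g)$support, dim = g$matrix_size)
  mid <- g$matrix_size[3] %/% 2
  slice_mask <- array(FALSE, dim = g$matrix_size)
  slice_mask[, , mid] <- sup[, , mid]
  for (i in 1:3) {
    coil_phase <- array(Arg(pre$data[, i, 1]), dim = g$matrix_size)
    n_res <- count_singularities(coil_phase, mask = slice_mask)$total
    expect_gte(n_res, 1)
    truth_phase <- array(Arg(truth$values[, i]), dim = g$matrix_size)
    expect_identical(count_singularities(truth_phase,
                                         mask = slice_mask)$total, 0L)
  }
})

test_that("targets share the prescan's physical sensitivities", {
  ph <- small_phantom(seed = 3, n = 12, n_coils = 6, order = 2, snr = Inf)
  est_t <- voxelwise_svd(ph$target)
  sup <- ph$support
  truth_vals <- eval_sensitivities(ph$truth, ph$target_geometry)
  # compare relative phases coil i vs coil 1 (common phase is arbitrary)
  idx <- which(sup & Mod(truth_vals[, 1]) > 0.3 &
                 Mod(est_t$c_prime[, 1]) > 0)[1:50]
  rel_est <- est_t$c_prime[idx, 2] * Conj(est_t$c_prime[idx, 1])
  rel_tru <- truth_vals[idx, 2] * Conj(truth_vals[idx, 1])
  dphi <- Arg(rel_est * Conj(rel_tru))
  expect_lt(max(abs(dphi)), 1e-8)

  # SVD across volumes at SNR 100 recovers truth phase differences closely
  ph2 <- small_phantom(seed = 4, n = 12, n_coils = 6, order = 2, snr = 100)
  est2 <- voxelwise_svd(ph2$target)
  tv2 <- eval_sensitivities(ph2$truth, ph2$target_geometry)
  idx2 <- which(ph2$support & Mod(tv2[, 1]) > 0.5 & Mod(tv2[, 2]) > 0.5)
  rel_est2 <- est2$c_prime[idx2, 2] * Conj(est2$c_prime[idx2, 1])
  rel_tru2 <- tv2[idx2, 2] * Conj(tv2[idx2, 1])
  rmse <- sqrt(mean(Arg(rel_est2 * Conj(rel_tru2))^2))
  expect_lt(rmse, 0.01)
})

test_that("generators are bit-reproducible and contrasts vary", {
  ph_a <- small_phantom(seed = 8, n = 8, n_coils = 3, snr = 30)
  ph_b <- small_phantom(seed = 8, n = 8, n_coils = 3, snr = 30)
  expect_identical(ph_a$prescan$data, ph_b$prescan$data)
  expect_identical(ph_a$target$data, ph_b$target$data)
  mags <- Mod(ph_a$scene$contrasts)
  expect_gt(max(mags) - min(mags), 0.1)   # large contrast variation
  expect_true(all(mags >= 0.2 & mags <= 1))
})
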