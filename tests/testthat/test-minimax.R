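test_that("single-coil minimax returns the smallest magnitude", {
  g <- vol_geometry(c(2, 1, 1), diag(4))
  est <- structure(list(c_prime = matrix(c(0.5 + 0i, 1 + 0i), ncol = 1),
                        lambda1 = c(1, 1), lambda2 = c(0, 0), geometry = g),
                   class = "sensitivity_estimate")
  mask <- structure(list(mask = c(TRUE, TRUE), threshold = 1,
                         provenance = "minimax", n = 2), class = "snr_mask")
  w <- solve_minimax(est, mask, restarts = 2, seed = 1)
  expect_equal(Mod(w$w), 1)
  expect_equal(w$achieved_min, 0.5, tolerance = 1e-9)
})

test_that("two orthogonal voxels: optimum is 1/sqrt(2), matching brute force", {
  g <- vol_geometry(c(2, 1, 1), diag(4))
  C <- rbind(c(1 + 0i, 0i), c(0i, 1 + 0i))
  est <- structure(list(c_prime = C, lambda1 = c(1, 1), lambda2 = c(0, 0),
                        geometry = g), class = "sensitivity_estimate")
  mask <- structure(list(mask = c(TRUE, TRUE), threshold = 1,
                         provenance = "minimax", n = 2), class = "snr_mask")
  w <- solve_minimax(est, mask, restarts = 4, seed = 2)

  # brute force over a dense grid of unit-norm w (phase of second component
  # is irrelevant for row magnitudes here)
  thetas <- seq(0, pi / 2, length.out = 2001)
  brute <- max(pmin(cos(thetas), sin(thetas)))
  expect_equal(brute, 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(w$achieved_min, 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(Mod(w$w), rep(1 / sqrt(2), 2), tolerance = 5e-3)
})

test_that("minimax escapes nulls that the SVD initialization leaves", {
  # 12 voxels aligned with coil 1, 9 with coil 2: the dominant singular
  # vector is e1, whose combination is null on the second cluster
  g <- vol_geometry(c(21, 1, 1), diag(4))
  C <- rbind(matrix(rep(c(1 + 0i, 0i), each = 12), ncol = 2),
             matrix(rep(c(0i, 1 + 0i), each = 9), ncol = 2))
  est <- structure(list(c_prime = C, lambda1 = rep(1, 21),
                        lambda2 = rep(0, 21), geometry = g),
                   class = "sensitivity_estimate")
  mask <- structure(list(mask = rep(TRUE, 21), threshold = 1,
                         provenance = "minimax", n = 21), class = "snr_mask")
  w <- solve_minimax(est, mask, restarts = 4, seed = 3)
  expect_equal(w$init_min, 0)
  expect_gt(w$achieved_min, 0.5)
})

test_that("achieved_min dominates the initialization on random problems", {
  set.seed(31)
  g <- vol_geometry(c(60, 1, 1), diag(4))
  mask <- structure(list(mask = rep(TRUE, 60), threshold = 1,
                         provenance = "minimax", n = 60), class = "snr_mask")
  for (rep in 1:10) {
    C <- matrix(complex(real = rnorm(60 * 6), imaginary = rnorm(60 * 6)),
                60, 6)
    C <- C / sqrt(rowSums(Mod(C)^2))
    est <- structure(list(c_prime = C, lambda1 = rep(1, 60),
                          lambda2 = rep(0, 60), geometry = g),
                     class = "sensitivity_estimate")
    w <- solve_minimax(est, mask, restarts = 3, seed = rep)
    expect_gte(w$achieved_min, w$init_min - 1e-12)
    expect_gt(w$achieved_min, 0)
    expect_equal(sum(Mod(w$w)^2), 1, tolerance = 1e-12)
  }
})

test_that("common-phase removal cancels phi_m exactly and preserves relative phases", {
  set.seed(17)
  g <- vol_geometry(c(40, 1, 1), diag(4))
  C <- matrix(complex(real = rnorm(40 * 4), imaginary = rnorm(40 * 4)), 40, 4)
  C <- C / sqrt(rowSums(Mod(C)^2))
  est <- structure(list(c_prime = C, lambda1 = rep(1, 40),
                        lambda2 = rep(0, 40), geometry = g),
                   class = "sensitivity_estimate")
  w <- random_unit_complex(4)
  al <- remove_common_phase(est, w)

  # formula oracle, element by element
  for (v in c(1, 7, 23)) {
    ref <- sum(Conj(w) * C[v, ])
    expect_equal(al$c_tilde[v, ], Conj(ref) * C[v, ], tolerance = 1e-14)
  }
  # w^H c_tilde is real and non-negative everywhere
  post <- al$c_tilde %*% Conj(w)
  expect_lt(max(abs(Im(post))), 1e-12)
  expect_true(all(Re(post) >= 0))

  # voxel-wise common phase perturbation leaves c_tilde unchanged
  psi <- runif(40, -pi, pi)
  est2 <- est
  est2$c_prime <- C * exp(1i * psi)
  al2 <- remove_common_phase(est2, w)
  expect_lt(max(Mod(al2$c_tilde - al$c_tilde)), 1e-12)

  # relative phases between coils are exactly those of c_prime
  rel_ct <- Arg(al$c_tilde[, 1] * Conj(al$c_tilde[, 2]))
  rel_cp <- Arg(C[, 1] * Conj(C[, 2]))
  expect_lt(max(abs(wrap_phase_test(rel_ct - rel_cp))), 1e-12)
})

test_that("the minimax reference is free of phase residues on vortex scenes", {
  ph <- standard_phantom(seed = 12, n_coils = 8, order = 2, snr = Inf,
                         prescan_n = 20, target_n = 20,
                         vortices = matrix(c(0, 0, 1), nrow = 1))
  est <- voxelwise_svd(ph$prescan)
  snr <- snr_map(est)
  mask <- snr_threshold_mask(snr, 20, "minimax")
  w <- solve_minimax(est, mask, restarts = 4, seed = 1)
  al <- remove_common_phase(est, w)
  # before alignment the estimated sensitivities carry the transmit vortex;
  # alignment removes it from every coil
  res_before <- count_singularities(Arg(est$c_prime[, 1]), mask = mask$mask,
                                    geometry = ph$prescan_geometry)$total
  res_after <- count_singularities(Arg(al$c_tilde[, 1]), mask = mask$mask,
                                   geometry = ph$prescan_geometry)$total
  expect_gte(res_before, 1L)
  expect_identical(res_after, 0L)
})
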