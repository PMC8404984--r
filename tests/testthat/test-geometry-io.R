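test_that("voxel/mm round trips are identity and constructor validates", {
  expect_error(vol_geometry(c(4, 4), diag(4)), "3 positive integers")
  expect_error(vol_geometry(c(4, 4, 4), matrix(0, 4, 4)), "singular")

  set.seed(11)
  for (i in 1:5) {
    aff <- diag(4)
    aff[1:3, 1:3] <- qr.Q(qr(matrix(rnorm(9), 3))) %*% diag(runif(3, 1, 8))
    aff[1:3, 4] <- rnorm(3, sd = 40)
    g <- vol_geometry(c(5, 6, 7), aff)
    ijk <- voxel_index_grid(g)
    back <- mm_to_voxel(g, voxel_to_mm(g, ijk))
    expect_lt(max(abs(back - ijk)), 1e-9)
  }
})

test_that("voxel_coordinates normalizes, scales, and is affine-equivariant", {
  g <- centered_geometry(9, 2)
  co <- voxel_coordinates(g, c0 = c(0, 0, 0), r0 = 1)
  expect_equal(colSums(co), c(x = 0, y = 0, z = 0))          # symmetric
  expect_equal(voxel_coordinates(g, r0 = 2), co / 2)         # r0 scaling
  expect_error(voxel_coordinates(g, r0 = 0), "positive")

  # shifted affine vs shifted c0 cancel exactly
  g2 <- g
  g2$affine[1:3, 4] <- g2$affine[1:3, 4] + c(5, -3, 2)
  expect_equal(voxel_coordinates(g2, c0 = c(5, -3, 2)), co)

  # rigid transform of the affine with matching c0 leaves coordinates
  # unchanged up to the rotation (dimensionless radii identical)
  set.seed(4)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  g3 <- g
  g3$affine[1:3, 1:3] <- Q %*% g$affine[1:3, 1:3]
  g3$affine[1:3, 4] <- Q %*% g$affine[1:3, 4] + c(1, 2, 3)
  co3 <- voxel_coordinates(g3, c0 = c(1, 2, 3))
  expect_lt(max(abs(sqrt(rowSums(co3^2)) - sqrt(rowSums(co^2)))), 1e-9)
})

test_that("complex NIfTI write/read round-trips data and affine exactly", {
  g <- tiny_geometry()
  set.seed(2)
  arr <- array(complex(real = rnorm(8^3 * 4 * 2),
                       imaginary = rnorm(8^3 * 4 * 2)),
               dim = c(8, 8, 8, 4, 2))
  cs <- coil_image_set(arr, g)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_coil_nifti(cs, path, "complex")
  back <- read_coil_nifti(path, "complex")
  expect_identical(as.vector(back$data), as.vector(cs$data))
  expect_true(all(back$geometry$affine == g$affine))
  expect_identical(back$coil_count, 4L)
  expect_identical(back$image_count, 2L)
})

test_that("pair layouts convert correctly and validate shapes", {
  g <- tiny_geometry()
  nv <- n_voxels(g)

  # mag all ones, phase all zeros -> identically 1+0i
  ones <- array(1, dim = c(g$matrix_size, 2))
  zeros <- array(0, dim = c(g$matrix_size, 2))
  p_mag <- withr::local_tempfile(fileext = ".nii.gz")
  p_phs <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(ones), p_mag)
  RNifti::writeNifti(RNifti::asNifti(zeros), p_phs)
  cs <- read_coil_nifti(c(p_mag, p_phs), "mag_phase_pair")
  expect_true(all(cs$data == 1 + 0i))

  # mismatched pair shapes produce a descriptive error naming the files
  bad <- array(0, dim = c(g$matrix_size, 3))
  p_bad <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(bad), p_bad)
  expect_error(read_coil_nifti(c(p_mag, p_bad), "mag_phase_pair"),
               "mismatched shapes")

  # mag/phase round trip through write_combined_nifti
  set.seed(3)
  v <- complex(real = rnorm(nv), imaginary = rnorm(nv))
  stem <- withr::local_tempfile(fileext = ".nii.gz")
  paths <- write_combined_nifti(v, g, stem, "mag_phase_pair")
  back <- read_combined_nifti(paths, "mag_phase_pair")
  expect_lt(max(Mod(back$values[, 1] - v)), 1e-12)
})

test_that("phase of -1 is written as +pi and of +1 as 0", {
  g <- tiny_geometry(4)
  nv <- n_voxels(g)
  stem <- withr::local_tempfile(fileext = ".nii.gz")
  paths <- write_combined_nifti(rep(-1 + 0i, nv), g, stem, "mag_phase_pair")
  expect_true(all(as.array(RNifti::readNifti(paths[2])) == pi))
  paths2 <- write_combined_nifti(rep(1 + 0i, nv), g,
                                 withr::local_tempfile(fileext = ".nii.gz"),
                                 "mag_phase_pair")
  expect_true(all(as.array(RNifti::readNifti(paths2[2])) == 0))
})

test_that("fit sidecar round-trips and re-evaluates identically", {
  ph <- small_phantom(seed = 5, n = 12, n_coils = 4, order = 1, snr = 100)
  est <- voxelwise_svd(ph$prescan)
  snr <- snr_map(est)
  w <- solve_minimax(est, snr_threshold_mask(snr, 5, "minimax"),
                     restarts = 2, seed = 1)
  aligned <- remove_common_phase(est, w)
  fit <- suppressWarnings(
    fit_variable_exchange(aligned, est$lambda1,
                          snr_threshold_mask(snr, 5, "fit"), order = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_sidecar(fit, path, extra = list(note = "test"))
  fit2 <- read_fit_sidecar(path)
  expect_equal(fit2$coefficients, fit$coefficients)
  expect_equal(fit2$c0, fit$c0)
  expect_equal(fit2$r0, fit$r0)
  e1 <- suppressWarnings(evaluate_fit(fit, ph$target_geometry)$sensitivities)
  e2 <- suppressWarnings(evaluate_fit(fit2, ph$target_geometry)$sensitivities)
  expect_lt(max(Mod(e1 - e2)), 1e-12)
})
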