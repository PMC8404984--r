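# Shared fixtures and independent oracles. Everything is generated in code;
# sizes are kept small so the default run stays fast.

tiny_geometry <- function(n = 8, voxel_mm = 8) centered_geometry(n, voxel_mm)

# Independent SVD oracle: eigen-decomposition of the Hermitian dilation
# [[0, S], [S^H, 0]], whose positive eigenvalues are the singular values and
# whose eigenvectors stack (u, v)/sqrt(2). Independent of LAPACK's SVD path.
svd_dilation_oracle <- function(S) {
  n <- nrow(S); m <- ncol(S)
  H <- rbind(cbind(matrix(0i, n, n), S),
             cbind(Conj(t(S)), matrix(0i, m, m)))
  e <- eigen(H, symmetric = TRUE)
  k <- min(n, m)
  vals <- e$values[seq_len(k)]
  u <- e$vectors[seq_len(n), seq_len(k), drop = FALSE] * sqrt(2)
  v <- e$vectors[n + seq_len(m), seq_len(k), drop = FALSE] * sqrt(2)
  list(d = vals, u = u, v = v)
}

# angle between complex one-dimensional subspaces, computed via the
# orthogonal residual so small angles are not lost to cancellation
subspace_angle <- function(a, b) {
  a <- a / sqrt(sum(Mod(a)^2))
  b <- b / sqrt(sum(Mod(b)^2))
  r <- b - sum(Conj(a) * b) * a
  asin(min(1, sqrt(sum(Mod(r)^2))))
}

# small complete phantom for integration-style tests
small_phantom <- function(seed = 1, n = 16, n_coils = 8, order = 2,
                          snr = Inf, n_images = 5, n_volumes = 3) {
  standard_phantom(seed = seed, n_coils = n_coils, order = order, snr = snr,
                   n_images = n_images, n_volumes = n_volumes,
                   prescan_n = n, target_n = n)
}

# directly-constructed aligned_sensitivities for fitting tests
make_aligned <- function(c_tilde, geometry, n_coils = ncol(c_tilde)) {
  structure(list(c_tilde = c_tilde,
                 weights = rep(1 / sqrt(n_coils) + 0i, n_coils),
                 reference = rep(1 + 0i, nrow(c_tilde)),
                 null_voxels = 0L, geometry = geometry),
            class = "aligned_sensitivities")
}

full_mask <- function(geometry) {
  nv <- n_voxels(geometry)
  structure(list(mask = rep(TRUE, nv), threshold = 1, provenance = "fit",
                 n = nv), class = "snr_mask")
}

wrap_phase_test <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

random_unit_complex <- function(n) {
  z <- complex(real = rnorm(n), imaginary = rnorm(n))
  z / sqrt(sum(Mod(z)^2))
}
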