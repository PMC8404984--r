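#' Real regular solid-harmonic basis
#'
#' Builds the design matrix of regular solid harmonics
#' `sqrt(4*pi/(2l+1)) * r^l * Y_lm` evaluated on dimensionless coordinates,
#' using the real (cos/sin) combinations for `m != 0` so the matrix is real
#' while spanning the same space as the complex harmonics. With the Schmidt
#' semi-normalization the columns reduce to harmonic polynomials:
#' `r^l * P_l(cos theta)` for `m = 0` and
#' `sqrt(2 (l-m)!/(l+m)!) * r^l * P_l^m(cos theta) * cos/sin(m phi)` for
#' `m > 0` (associated Legendre functions with the Condon-Shortley phase,
#' as returned by [pracma::legendre()]).
#'
#' Columns are ordered with `l` ascending and, within each `l`, `m` from
#' `-l` to `l`; negative `m` are the `sin(|m| phi)` terms. This order is
#' fixed and recorded in fit sidecars so coefficients are portable. The
#' order-0 column is identically 1 and there are `(N+1)^2` columns in total.
#' Every column satisfies Laplace's equation exactly (they are harmonic
#' polynomials); at the coordinate origin the `l > 0` columns vanish.
#'
#' @param coords n x 3 matrix of dimensionless coordinates (see
#'   [voxel_coordinates()]).
#' @param order maximal degree `N >= 0`.
#' @return an object of class `harmonic_basis`: list with `A`
#'   (n x (N+1)^2 numeric design matrix), `order`, and `lm` (two-column
#'   matrix giving each column's `(l, m)`).
#' @export
build_basis <- function(coords, order) {
  if (!is.numeric(order) || length(order) != 1L || order < 0 ||
      order != round(order))
    stop("order must be a non-negative integer")
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  n <- nrow(coords)
  r <- sqrt(rowSums(coords^2))
  cost <- ifelse(r > 0, coords[, 3] / r, 1)
  cost <- pmin(1, pmax(-1, cost))
  phi <- atan2(coords[, 2], coords[, 1])

  n_terms <- (order + 1)^2
  A <- matrix(0, n, n_terms)
  lm <- matrix(0L, n_terms, 2)
  col <- 1L
  for (l in 0:order) {
    rl <- if (l == 0) rep(1, n) else r^l
    P <- if (l == 0) matrix(1, 1, n) else pracma::legendre(l, cost)
    # m from -l to l: sin terms, zonal, cos terms
    if (l > 0) for (m in l:1) {
      norm <- sqrt(2 * factorial(l - m) / factorial(l + m))
      A[, col] <- norm * rl * P[m + 1, ] * sin(m * phi)
      lm[col, ] <- c(l, -m)
      col <- col + 1L
    }
    A[, col] <- rl * P[1, ]
    lm[col, ] <- c(l, 0L)
    col <- col + 1L
    if (l > 0) for (m in 1:l) {
      norm <- sqrt(2 * factorial(l - m) / factorial(l + m))
      A[, col] <- norm * rl * P[m + 1, ] * cos(m * phi)
      lm[col, ] <- c(l, m)
      col <- col + 1L
    }
  }
  structure(list(A = A, order = as.integer(order), lm = lm),
            class = "harmonic_basis")
}

#' Fit aligned sensitivities to the solid-harmonic basis by variable exchange
#'
#' Solves the joint problem
#' `min_{X, d} || W (A X - diag(d) C_tilde) ||_F^2  s.t.  d^H d = k`
#' where `A` is the solid-harmonic design matrix on the masked voxels, `X`
#' the complex coefficients per coil, `d` a free per-voxel complex scaling
#' (the residual virtual-reference-coil component, which does not carry
#' relative phase information), `W` the per-voxel weights `sqrt(lambda1)`,
#' and `k` the number of fitted voxels. The norm constraint on `d` excludes
#' the trivial `X = 0, d = 0` solution.
#'
#' The exchange alternates: (a) weighted complex least squares for `X`
#' given `d`; (b) the exact norm-constrained least-squares update of `d`
#' given `X` (per-voxel shrinkage `d_v = n_v / (a_v + mu)` with the
#' Lagrange multiplier `mu` solved so that `||d||^2 = k`). Both steps
#' decrease the weighted objective, so the residual history is
#' non-increasing by construction and `||d||^2 = k` holds after every
#' iteration. `d` is initialized to all ones. Iteration stops when the
#' residual changes by less than `tol` (relative; default 0.01%).
#'
#' Voxels with zero `c_tilde` or zero weight are excluded from the fit
#' rows. The convex hull of the fitted voxels (in mm) is attached for later
#' application to other geometries.
#'
#' @param aligned an [remove_common_phase()] result.
#' @param lambda1 per-voxel first singular values (fit weights are their
#'   square roots).
#' @param fit_mask an [snr_threshold_mask()].
#' @param order solid-harmonic order `N`; `(N+1)^2` coefficients per coil.
#' @param tol relative residual-change stopping tolerance (default `1e-4`,
#'   i.e. 0.01%).
#' @param max_iter maximum exchange iterations.
#' @return an object of class `harmonic_fit`: `coefficients` (complex
#'   `(N+1)^2` x coil), `d`, `residual_history` (weighted objective after
#'   each X-step), `relative_residual`, `converged`, `iterations`, `order`,
#'   `c0`, `r0`, `hull`, `voxels` (linear indices of fitted voxels),
#'   `weights_ref` (the reference weights used for alignment), `geometry`.
#' @export
fit_variable_exchange <- function(aligned, lambda1, fit_mask, order = 6,
                                  tol = 1e-4, max_iter = 100) {
  stopifnot(inherits(aligned, "aligned_sensitivities"),
            inherits(fit_mask, "snr_mask"))
  keep <- which(fit_mask$mask)
  Ct <- aligned$c_tilde[keep, , drop = FALSE]
  wts <- sqrt(pmax(lambda1[keep], 0))
  good <- rowSums(Mod(Ct)) > 0 & wts > 0
  keep <- keep[good]
  Ct <- Ct[good, , drop = FALSE]
  wts <- wts[good]
  k <- length(keep)
  n_terms <- (order + 1)^2
  if (k == 0) stop("fit mask is empty after excluding degenerate voxels")
  if (n_terms > k)
    stop("order ", order, " needs ", n_terms, " coefficients but only ", k,
         " voxels are masked")

  geom <- aligned$geometry
  mm <- voxel_to_mm(geom)[keep, , drop = FALSE]
  c0 <- colMeans(mm)
  r0 <- max(sqrt(rowSums(sweep(mm, 2, c0)^2)))
  if (r0 <= 0) stop("fitted voxels geometrically degenerate (single point)")
  basis <- build_basis(sweep(mm, 2, c0) / r0, order)
  A <- basis$A

  wts <- wts / mean(wts)  # scale-free weights
  Aw <- A * wts
  AtA <- crossprod(Aw)
  cn <- kappa(AtA, exact = FALSE)
  R <- tryCatch(chol(AtA), error = function(e)
    stop("solid-harmonic design is rank deficient on the masked voxels ",
         "(condition number ~ ", signif(cn, 3), ")"))

  d <- rep(1 + 0i, k)
  d <- d * sqrt(k) / sqrt(sum(Mod(d)^2))
  history <- numeric(0)
  converged <- FALSE
  res_prev <- Inf
  target_norm2 <- NULL
  X <- NULL
  for (it in seq_len(max_iter)) {
    # (a) X given d: weighted complex least squares
    Tw <- (wts * d) * Ct
    rhs <- crossprod(Aw, Tw)
    chol_solve <- function(b) backsolve(R, backsolve(R, b, transpose = TRUE))
    X <- chol_solve(Re(rhs)) + 1i * chol_solve(Im(rhs))
    Rfit <- Aw %*% X - Tw
    J <- sum(Mod(Rfit)^2)
    history <- c(history, J)
    target_norm2 <- sum(Mod(Tw)^2)
    res <- sqrt(J)
    if (res <= 1e-12 * sqrt(target_norm2)) {  # exact fit: nothing left
      converged <- TRUE
      break
    }
    if (is.finite(res_prev)) {
      denom <- max(res_prev, sqrt(target_norm2) * 1e-15)
      if (abs(res_prev - res) / denom < tol || res_prev == 0) {
        converged <- TRUE
        break
      }
    }
    res_prev <- res
    if (it == max_iter) break
    # (b) d given X: norm-constrained least squares
    AX <- A %*% X
    d <- constrained_d_update(AX, Ct, wts^2, k)
  }
  if (!converged)
    warning("variable exchange did not converge in ", max_iter, " iterations")

  hull <- build_hull(keep, geom)
  structure(list(coefficients = X,
                 d = d,
                 residual_history = history,
                 relative_residual = sqrt(history[length(history)] /
                                            max(target_norm2, 1e-300)),
                 converged = converged,
                 iterations = length(history),
                 order = as.integer(order),
                 n_terms = n_terms,
                 lm = basis$lm,
                 c0 = as.numeric(c0), r0 = as.numeric(r0),
                 hull = hull,
                 voxels = keep,
                 condition_number = cn,
                 weights_ref = aligned$weights,
                 geometry = geom),
            class = "harmonic_fit")
}

# Exact solution of min_d sum_v w2_v |AX_v - d_v ct_v|^2 s.t. sum |d_v|^2 = k.
# Separable quadratic plus a sphere constraint: d_v = n_v / (a_v + mu) with
# mu the Lagrange multiplier solving sum |n_v|^2 / (a_v + mu)^2 = k.
constrained_d_update <- function(AX, Ct, w2, k) {
  nv <- w2 * rowSums(Conj(Ct) * AX)   # c~_v^H (AX)_v, weighted
  av <- w2 * rowSums(Mod(Ct)^2)
  nz <- Mod(nv) > 0
  if (!any(nz))
    stop("d-update degenerate: model orthogonal to data at every voxel")
  g <- function(mu) sum((Mod(nv[nz]) / (av[nz] + mu))^2) - k
  amin <- min(av[nz])
  lo <- -amin + max(amin, 1) * 1e-12
  if (g(0) >= 0) {
    hi <- sqrt(sum(Mod(nv)^2) / k)  # guarantees g(hi) <= 0
    lo <- 0
  } else {
    hi <- 0
    gap <- amin * 1e-8
    repeat {
      lo <- -amin + gap
      if (g(lo) >= 0 || gap < amin * 1e-300) break
      gap <- gap / 100
    }
    if (g(lo) < 0) {
      # cannot reach norm k numerically: scale the unconstrained optimum
      d <- nv / av
      return(d * sqrt(k / sum(Mod(d)^2)))
    }
  }
  mu <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.75,
                       maxiter = 2000)$root
  d <- nv / (av + mu)
  d * sqrt(k / sum(Mod(d)^2))  # tidy rounding of the constraint
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat("harmonic_fit: order", x$order, "(", x$n_terms, "terms ) x",
      ncol(x$coefficients), "coils;", length(x$voxels), "voxels;",
      x$iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("relative residual:", signif(x$relative_residual, 4), "\n")
  invisible(x)
}
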