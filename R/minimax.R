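#' Minimax virtual reference coil weights
#'
#' Finds unit-norm coil weights `w` that (approximately) maximize the
#' minimum combined magnitude `min_k |w^H c'_k|` over the masked voxels.
#' The combination `w^H C'` serves as a virtual reference coil: because it
#' is a linear combination of the estimated sensitivities it carries the
#' same arbitrary common phase `phi_m`, and because the minimax objective
#' forbids nulls inside the mask, dividing it out cannot introduce phase
#' singularities of its own.
#'
#' The objective is piecewise smooth; it is ascended with a log-sum-exp
#' smoothed minimum whose sharpness is annealed (doubling per stage), with
#' projected gradient steps on the unit sphere and backtracking on the true
#' (unsmoothed) objective. The solver is initialized from the dominant left
#' singular vector of the masked sensitivity stack and restarted from
#' seeded random directions; the best iterate is kept, so the achieved
#' minimum is guaranteed to be at least that of the initialization and
#' strictly positive on valid runs.
#'
#' @param estimate a [voxelwise_svd()] estimate.
#' @param mask an [snr_threshold_mask()] (typically the minimax mask).
#' @param restarts number of seeded random restarts in addition to the
#'   SVD initialization.
#' @param seed integer seed for the restarts.
#' @param sharpness numeric vector of annealing sharpness values.
#' @param max_iter gradient steps per sharpness stage.
#' @return object of class `reference_weights`: list with `w` (unit-norm
#'   complex coil vector), `achieved_min`, `init_min`, `iterations`,
#'   `restarts`.
#' @export
solve_minimax <- function(estimate, mask, restarts = 8, seed = 1,
                          sharpness = 2 * 2^(0:5), max_iter = 60) {
  stopifnot(inherits(estimate, "sensitivity_estimate"),
            inherits(mask, "snr_mask"))
  C <- estimate$c_prime[mask$mask, , drop = FALSE]
  if (nrow(C) == 0) stop("minimax mask is empty")
  n_coil <- ncol(C)

  objective <- function(w) min(Mod(C %*% Conj(w)))

  ascend <- function(w) {
    iters <- 0L
    f <- objective(w)
    for (beta in sharpness) {
      step <- 0.5
      for (it in seq_len(max_iter)) {
        a <- as.vector(C %*% Conj(w))
        g <- Mod(a)
        gm <- pmax(g, 1e-300)
        p <- exp(-beta * (g - min(g)))
        p <- p / sum(p)
        grad <- crossprod(C, p * Conj(a) / gm)  # t(C) %*% ...
        grad <- as.vector(grad)
        improved <- FALSE
        while (step > 1e-6) {
          w_new <- w + step * grad / max(sqrt(sum(Mod(grad)^2)), 1e-300)
          w_new <- w_new / sqrt(sum(Mod(w_new)^2))
          f_new <- objective(w_new)
          if (f_new > f) {
            w <- w_new; f <- f_new
            improved <- TRUE
            step <- min(step * 2, 1)
            break
          }
          step <- step / 2
        }
        iters <- iters + 1L
        if (!improved) break
      }
    }
    list(w = w, f = f, iters = iters)
  }

  # initialization: dominant left singular vector of the coil x voxel stack
  M <- crossprod(Conj(C), C)  # n_coil x n_coil, C^H C
  w0 <- eigen(M, symmetric = TRUE)$vectors[, 1]
  w0 <- w0 / sqrt(sum(Mod(w0)^2))
  init_min <- objective(w0)

  best <- ascend(w0)
  total_iters <- best$iters
  starts <- with_seed(seed, lapply(seq_len(restarts), function(i) {
    z <- complex(real = stats::rnorm(n_coil),
                 imaginary = stats::rnorm(n_coil))
    z / sqrt(sum(Mod(z)^2))
  }))
  for (w_start in starts) {
    cand <- ascend(w_start)
    total_iters <- total_iters + cand$iters
    if (cand$f > best$f) best <- cand
  }

  if (best$f <= 0)
    stop("minimax failed: every candidate reference has a null inside the ",
         "mask (degenerate sensitivity geometry)")
  structure(list(w = best$w, achieved_min = best$f, init_min = init_min,
                 iterations = total_iters, restarts = restarts, seed = seed),
            class = "reference_weights")
}

#' @export
print.reference_weights <- function(x, ...) {
  cat("reference_weights:", length(x$w), "coils, achieved min",
      signif(x$achieved_min, 4), "(init", paste0(signif(x$init_min, 4), ")"),
      "\n")
  invisible(x)
}

#' Remove the common phase using reference weights
#'
#' Applies `c_tilde = conj(w^H c') * c'` voxel-wise. Any phase common to all
#' coils at a voxel (the magnetization/B1+ phase `phi_m`) cancels exactly:
#' multiplying every coil of a voxel by `exp(1i * gamma)` leaves `c_tilde`
#' unchanged, while relative phases between coils are preserved exactly.
#' After the correction `w^H c_tilde` is real and non-negative at every
#' voxel where `w^H c'` is nonzero.
#'
#' @param estimate a [voxelwise_svd()] estimate.
#' @param weights a [solve_minimax()] result (or any unit-norm complex coil
#'   vector).
#' @return object of class `aligned_sensitivities`: list with `c_tilde`
#'   (voxel x coil complex), `weights`, `null_voxels` (count of voxels where
#'   `w^H c' == 0`, flagged, set to zero), `geometry`.
#' @export
remove_common_phase <- function(estimate, weights) {
  stopifnot(inherits(estimate, "sensitivity_estimate"))
  w <- if (inherits(weights, "reference_weights")) weights$w else weights
  if (abs(sqrt(sum(Mod(w)^2)) - 1) > 1e-8)
    stop("reference weights must have unit norm")
  ref <- as.vector(estimate$c_prime %*% Conj(w))  # w^H c' per voxel
  c_tilde <- Conj(ref) * estimate$c_prime
  structure(list(c_tilde = c_tilde,
                 weights = w,
                 reference = ref,
                 null_voxels = sum(ref == 0 & estimate$lambda1 > 0),
                 geometry = estimate$geometry),
            class = "aligned_sensitivities")
}

#' @export
print.aligned_sensitivities <- function(x, ...) {
  cat("aligned_sensitivities:", nrow(x$c_tilde), "voxels,",
      ncol(x$c_tilde), "coils;", x$null_voxels, "null voxels\n")
  invisible(x)
}
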