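# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards, so generators are bit-reproducible without
# disturbing the session.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Wrap angles to (-pi, pi].
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Standard complex Gaussian noise: E|z|^2 = sd^2.
complex_noise <- function(n, sd) {
  complex(real = stats::rnorm(n, sd = sd / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sd / sqrt(2)))
}
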