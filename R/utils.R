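# Internal helpers: seeded RNG scopes, log-normal noise, truncated normals,
# Wilson intervals.

# Evaluate expr with the RNG seeded to `seed`, restoring global RNG state on
# exit. All user-facing randomness flows through this; no function leaves the
# global .Random.seed perturbed.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed derivation; keeps values in valid 32-bit range.
subSeed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483647)
}

# Mean-preserving multiplicative log-normal noise with coefficient of
# variation `cv`: E[X] = 1 and sd(X)/E[X] = cv exactly.
lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, 0, s) - s^2 / 2)
}

# Gaussian truncated at zero (proper truncation, not clipping).
rtnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(pmax(mean, 0), length.out = n))
  lo <- stats::pnorm(0, mean, sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, 1))
}

# 95% Wilson score interval (no continuity correction), vectorised over x.
wilsonCI <- function(x, n, conf = 0.95) {
  if (n == 0L) return(matrix(NA_real_, length(x), 2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(pmax(center - half, 0), pmin(center + half, 1))
}

# Half-open [lo, hi) membership.
inInterval <- function(x, interval) x >= interval[1] & x < interval[2]

`%||%` <- function(a, b) if (is.null(a)) b else a
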