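# Internal helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so package functions never perturb the
# session RNG. `seed = NULL` uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Draw one multivariate normal vector with covariance `sigma` (dense, PD
# after an optional nugget). Uses the upper Cholesky factor.
rmvn1 <- function(mu, sigma) {
  n <- length(mu)
  if (n == 1L) return(mu + sqrt(sigma[1, 1]) * stats::rnorm(1))
  R <- chol(sigma)
  drop(mu + crossprod(R, stats::rnorm(n)))
}

# Log density of y ~ N(mu, sigma) via Cholesky; returns -Inf if sigma is
# not positive definite.
ldmvn <- function(y, mu, sigma) {
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  z <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# Inverse-gamma log density (shape a, scale b) at x > 0.
ldinvgamma <- function(x, a, b) {
  ifelse(x > 0, a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x, -Inf)
}
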