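# internal numerical helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# log-density of a multivariate normal via the Cholesky factor; kept internal
# (the small standard formula, used by the filter oracle and the marginal
# likelihood). `label` names the offending block on failure.
dmvnorm_log <- function(x, mean, sigma, label = "covariance") {
  r <- x - mean
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop(sprintf("%s is not positive definite", label), call. = FALSE)
  })
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# draw n samples from N(mean, sigma); rows are draws
rmvnorm_chol <- function(n, mean, sigma) {
  d <- length(mean)
  if (d == 0L) return(matrix(0, n, 0L))
  ch <- chol(sigma)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% ch, 2L, mean, `+`)
}

is_square_matrix <- function(m) is.matrix(m) && nrow(m) == ncol(m)

# symmetric positive-semidefinite check with a small tolerance
is_valid_corr <- function(R, tol = 1e-8) {
  is_square_matrix(R) &&
    all(is.finite(R)) &&
    max(abs(R - t(R))) < tol &&
    max(abs(diag(R) - 1)) < tol &&
    min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > -tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
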