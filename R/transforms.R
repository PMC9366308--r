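#' Parameter transforms between unconstrained and natural scales
#'
#' Population-level estimation works on an unconstrained real vector; each
#' model parameter has a bijective link to its natural scale:
#' identity for manifest means, the practice-effect increment and the practice
#' self-feedback rate; `softplus` for standard deviations (diffusion and
#' measurement error); negative softplus for the trial self-feedback rate
#' (which must be negative for the stationary baseline covariance to exist);
#' and a canonical-partial-correlation map for correlation matrices.
#'
#' @param x,y numeric vectors.
#' @return `softplus()` maps reals to positives, `softplus_inv()` is its
#'   inverse; round-trip error is below 1e-10 over the usable range.
#' @examples
#' softplus_inv(softplus(1.3))
#' @export
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' @rdname softplus
#' @export
softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

# derivative of softplus, used for prior Jacobians and gradients
softplus_deriv <- function(x) stats::plogis(x)

#' Unconstrained parameterization of a correlation matrix
#'
#' Maps a real vector of length `d*(d-1)/2` to a `d x d` correlation matrix
#' through tanh-transformed canonical partial correlations and a Cholesky
#' construction, and back. The map is bijective onto the set of strictly
#' positive-definite correlation matrices; the zero vector maps to the
#' identity.
#'
#' @param z real vector of length `d*(d-1)/2` (row-wise lower triangle order).
#' @param d dimension of the correlation matrix.
#' @param R a positive-definite correlation matrix.
#' @return `corr_from_unconstrained()` returns a correlation matrix;
#'   `corr_to_unconstrained()` returns the unconstrained vector.
#' @examples
#' R <- corr_from_unconstrained(c(0.5, -0.2, 0.1), d = 3)
#' max(abs(corr_from_unconstrained(corr_to_unconstrained(R), 3) - R))
#' @export
corr_from_unconstrained <- function(z, d) {
  stopifnot(length(z) == d * (d - 1) / 2, all(is.finite(z)))
  x <- tanh(z)
  L <- matrix(0, d, d)
  L[1, 1] <- 1
  idx <- 1L
  for (i in seq_len(d)[-1L]) {
    for (j in seq_len(i - 1L)) {
      rem <- 1 - sum(L[i, seq_len(j - 1L)]^2)
      L[i, j] <- x[idx] * sqrt(rem)
      idx <- idx + 1L
    }
    L[i, i] <- sqrt(1 - sum(L[i, seq_len(i - 1L)]^2))
  }
  R <- L %*% t(L)
  diag(R) <- 1
  (R + t(R)) / 2
}

#' @rdname corr_from_unconstrained
#' @export
corr_to_unconstrained <- function(R) {
  stopifnot(is_valid_corr(R))
  d <- nrow(R)
  L <- t(chol(R))
  z <- numeric(d * (d - 1) / 2)
  idx <- 1L
  for (i in seq_len(d)[-1L]) {
    for (j in seq_len(i - 1L)) {
      rem <- 1 - sum(L[i, seq_len(j - 1L)]^2)
      z[idx] <- atanh(max(min(L[i, j] / sqrt(rem), 1 - 1e-12), -1 + 1e-12))
      idx <- idx + 1L
    }
  }
  z
}

# link table: one entry per scalar model parameter (correlations are handled
# separately as blocks). Applies elementwise to a named unconstrained vector.
param_links <- function(names) {
  link <- rep("identity", length(names))
  link[grepl("^diffusion_t[1-4]$|^meas_error$", names)] <- "softplus"
  link[names == "sf_trial"] <- "neg_softplus"
  stats::setNames(link, names)
}

apply_link <- function(u, link) {
  switch(link,
    identity = u,
    softplus = softplus(u),
    neg_softplus = -softplus(u),
    stop("unknown link: ", link)
  )
}

apply_link_inv <- function(v, link) {
  switch(link,
    identity = v,
    softplus = softplus_inv(v),
    neg_softplus = softplus_inv(-v),
    stop("unknown link: ", link)
  )
}

# vectorized over a named parameter vector
natural_from_unconstrained <- function(u) {
  links <- param_links(names(u))
  out <- u
  for (i in seq_along(u)) out[i] <- apply_link(u[i], links[i])
  out
}

unconstrained_from_natural <- function(v) {
  links <- param_links(names(v))
  out <- v
  for (i in seq_along(v)) out[i] <- apply_link_inv(v[i], links[i])
  out
}
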