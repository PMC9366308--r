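# Exact Gaussian marginal likelihood of one subject's scores.
#
# Two independent routes are provided on purpose: a sequential Kalman filter
# over the 5-dimensional latent state, and a joint multivariate-normal
# evaluation that stacks all observed entries and composes the discrete-time
# blocks directly. They must agree to numerical precision; the test suite
# exercises this equivalence on randomized instances.

# floor added to the measurement variance so noise-free degenerate settings
# stay well defined in both routes
.var_floor <- 1e-8

#' Kalman-filter log-likelihood of a subject record
#'
#' Evaluates `log p(observed scores | spec)` by filtering the 5-dimensional
#' latent state (four trial deviations plus the practice level) across
#' occasions. The latent trial block is initialized at its scaled stationary
#' covariance, transitions use the matrix-exponential discretization, missing
#' trials are handled by row-deleting the observation equation, and the
#' practice increment is applied to the state mean after each occasion's
#' update (observations use the pre-increment practice level).
#'
#' @param spec a [dynamic_spec()] with negative `drift_trial`.
#' @param record a [subject_record()].
#' @param diagnostics return per-occasion filter quantities alongside the
#'   log-likelihood.
#' @return the log-likelihood in nats, or (with `diagnostics = TRUE`) a list
#'   with elements `loglik` and `occasions` (per-occasion predicted
#'   mean/covariance, innovation, innovation covariance and log-density
#'   contribution).
#' @seealso [joint_gaussian_oracle()] for the equivalent joint evaluation.
#' @export
kalman_loglik <- function(spec, record, diagnostics = FALSE) {
  stopifnot(inherits(record, "subject_record"))
  validate_dynamic_spec(spec)
  K <- length(record$times)
  Hfull <- cbind(diag(4), spec$practice_loading)
  A <- drift_matrix(spec)
  Q <- diffusion_matrix(spec)
  P <- matrix(0, 5, 5)
  P[1:4, 1:4] <- spec$initial_state_sd_scale^2 * stationary_cov_trials(spec)
  m <- numeric(5)
  r2 <- spec$meas_error_sd^2 + .var_floor
  ll <- 0
  occ <- vector("list", K)
  for (k in seq_len(K)) {
    if (k > 1L) {
      d <- discretize_matrix(A, Q, record$times[k] - record$times[k - 1L])
      m <- drop(d$transition %*% m)
      P <- d$transition %*% P %*% t(d$transition) + d$noise_cov
      P <- (P + t(P)) / 2
    }
    pred_m <- m
    pred_P <- P
    obs <- which(!is.na(record$scores[, k]))
    contrib <- 0
    innov <- NULL
    S <- NULL
    if (length(obs) > 0L) {
      H <- Hfull[obs, , drop = FALSE]
      S <- H %*% P %*% t(H) + diag(r2, length(obs))
      innov <- record$scores[obs, k] - (spec$manifest_mean[obs] + drop(H %*% m))
      ch <- tryCatch(chol(S), error = function(e) {
        stop(sprintf(
          "innovation covariance not positive definite at occasion %d", k
        ), call. = FALSE)
      })
      z <- backsolve(ch, innov, transpose = TRUE)
      contrib <- -0.5 * length(obs) * log(2 * pi) - sum(log(diag(ch))) -
        0.5 * sum(z^2)
      ll <- ll + contrib
      Kg <- P %*% t(H) %*% chol2inv(ch)
      m <- m + drop(Kg %*% innov)
      P <- P - Kg %*% H %*% P
      P <- (P + t(P)) / 2
    }
    if (diagnostics) {
      occ[[k]] <- list(predicted_mean = pred_m, predicted_cov = pred_P,
                       innovation = innov, innovation_cov = S,
                       log_density = contrib)
    }
    m[5L] <- m[5L] + spec$practice_gain  # post-observation practice increment
  }
  if (diagnostics) list(loglik = ll, occasions = occ) else ll
}

# joint mean vector and covariance matrix of all 4K potential observations,
# built by composing discretize_matrix() blocks across occasions; entries are
# ordered occasion-major (occasion 1 trials 1-4, occasion 2 trials 1-4, ...)
joint_obs_moments <- function(spec, times) {
  K <- length(times)
  A <- drift_matrix(spec)
  Q <- diffusion_matrix(spec)
  Hfull <- cbind(diag(4), spec$practice_loading)
  P0 <- matrix(0, 5, 5)
  P0[1:4, 1:4] <- spec$initial_state_sd_scale^2 * stationary_cov_trials(spec)
  lev <- practice_expectation(spec$practice_gain, spec$drift_practice, times)

  Pk <- vector("list", K)  # marginal latent covariances
  Pk[[1L]] <- P0
  steps <- vector("list", K)
  if (K > 1L) {
    for (k in 2:K) {
      d <- discretize_matrix(A, Q, times[k] - times[k - 1L])
      steps[[k]] <- d$transition
      Pk[[k]] <- d$transition %*% Pk[[k - 1L]] %*% t(d$transition) +
        d$noise_cov
      Pk[[k]] <- (Pk[[k]] + t(Pk[[k]])) / 2
    }
  }
  mu <- numeric(4L * K)
  sigma <- matrix(0, 4L * K, 4L * K)
  r2 <- spec$meas_error_sd^2 + .var_floor
  idx <- function(k) ((k - 1L) * 4L + 1L):(k * 4L)
  for (k in seq_len(K)) {
    mu[idx(k)] <- spec$manifest_mean + spec$practice_loading * lev[k]
    sigma[idx(k), idx(k)] <- Hfull %*% Pk[[k]] %*% t(Hfull) + diag(r2, 4)
    if (k < K) {
      trans <- diag(5)
      for (j in (k + 1L):K) {
        trans <- steps[[j]] %*% trans   # transition from occasion k to j
        cross <- Hfull %*% Pk[[k]] %*% t(trans) %*% t(Hfull)
        sigma[idx(k), idx(j)] <- cross
        sigma[idx(j), idx(k)] <- t(cross)
      }
    }
  }
  list(mean = mu, cov = (sigma + t(sigma)) / 2)
}

#' Joint-Gaussian evaluation of a subject's log-likelihood
#'
#' Builds the full joint mean and covariance of all observed score entries by
#' composing [discretize_matrix()] blocks and deterministic practice
#' increments across occasions, then evaluates a single multivariate-normal
#' log-density. Intended for small instances (few occasions) and as an
#' independent cross-check of [kalman_loglik()]; the two agree to 1e-8.
#'
#' @inheritParams kalman_loglik
#' @return log-likelihood in nats.
#' @export
joint_gaussian_oracle <- function(spec, record) {
  stopifnot(inherits(record, "subject_record"))
  validate_dynamic_spec(spec)
  K <- length(record$times)
  if (K > 8L) stop("joint_gaussian_oracle is for small instances (K <= 8)")
  jm <- joint_obs_moments(spec, record$times)
  y <- as.vector(record$scores)          # occasion-major (column) order
  obs <- which(!is.na(y))
  dmvnorm_log(y[obs], jm$mean[obs], jm$cov[obs, obs, drop = FALSE],
              label = "joint observation covariance")
}

#' Total log-likelihood over a set of subjects
#'
#' @param spec_resolver a function mapping a [subject_record()] to that
#'   subject's [dynamic_spec()] (e.g. resolving diagnosis and covariate
#'   moderation), or a single `dynamic_spec` shared by all subjects.
#' @param records list of subject records.
#' @return sum of per-subject log-likelihoods (nats); invariant to subject
#'   ordering. A failure for any subject is re-raised with its `subject_id`.
#' @export
dataset_loglik <- function(spec_resolver, records) {
  if (inherits(spec_resolver, "dynamic_spec")) {
    fixed <- spec_resolver
    spec_resolver <- function(record) fixed
  }
  stopifnot(is.function(spec_resolver), length(records) > 0L)
  sum(vapply(records, function(r) {
    tryCatch(kalman_loglik(spec_resolver(r), r), error = function(e) {
      stop(sprintf("subject %s: %s", r$subject_id, conditionMessage(e)),
           call. = FALSE)
    })
  }, numeric(1)))
}
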