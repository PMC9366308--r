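#' Continuous-time dynamic specification for one subject
#'
#' Describes the latent system underlying repeated verbal-recall testing:
#' four trial processes (three immediate recall trials and one delayed trial
#' of a 12-word list) modelled as Ornstein-Uhlenbeck deviations around
#' per-trial manifest means, plus a practice process that receives a
#' deterministic increment (`practice_gain`, in words) at the end of every
#' measurement occasion and evolves between occasions at rate
#' `drift_practice` (per year). Trial deviations share the self-feedback
#' rate `drift_trial` and are driven by correlated Wiener disturbances with
#' per-trial standard deviations `diffusion_sd` (words per sqrt(year)) and
#' correlation matrix `diffusion_corr`. Observed scores add the practice
#' level (through `practice_loading`) and i.i.d. Gaussian measurement error.
#'
#' @param drift_trial shared self-feedback rate of the four trial processes
#'   (per year); must be negative for the stationary baseline covariance used
#'   to initialize the latent state to exist (a warning is raised otherwise).
#' @param drift_practice self-feedback rate of the practice process (per
#'   year); positive values compound practice gains across occasions,
#'   negative values make them decay.
#' @param diffusion_sd length-4 vector of diffusion standard deviations.
#' @param diffusion_corr 4x4 correlation matrix of the trial disturbances.
#' @param manifest_mean length-4 vector of per-trial mean scores (words).
#' @param meas_error_sd scalar measurement-error standard deviation (words),
#'   shared across trials.
#' @param practice_gain practice increment applied after each occasion
#'   (words per occasion).
#' @param practice_loading length-4 loading of the practice level onto each
#'   trial's observation (default all 1).
#' @param initial_state_sd_scale dimensionless multiplier applied to the
#'   stationary standard deviation of the trial deviations at baseline.
#' @return an object of class `dynamic_spec`.
#' @examples
#' spec <- dynamic_spec(
#'   drift_trial = -3.5, drift_practice = 0, diffusion_sd = rep(2, 4),
#'   diffusion_corr = diag(4), manifest_mean = c(6, 8.8, 9.8, 8.5),
#'   meas_error_sd = 0.3, practice_gain = 0.4
#' )
#' spec
#' @export
dynamic_spec <- function(drift_trial, drift_practice, diffusion_sd,
                         diffusion_corr, manifest_mean, meas_error_sd,
                         practice_gain, practice_loading = rep(1, 4),
                         initial_state_sd_scale = 1) {
  spec <- structure(
    list(
      drift_trial = drift_trial,
      drift_practice = drift_practice,
      diffusion_sd = as.numeric(diffusion_sd),
      diffusion_corr = diffusion_corr,
      manifest_mean = as.numeric(manifest_mean),
      meas_error_sd = meas_error_sd,
      practice_gain = practice_gain,
      practice_loading = as.numeric(practice_loading),
      initial_state_sd_scale = initial_state_sd_scale
    ),
    class = "dynamic_spec"
  )
  validate_dynamic_spec(spec)
  spec
}

validate_dynamic_spec <- function(spec) {
  with(spec, {
    vals <- c(drift_trial, drift_practice, diffusion_sd, manifest_mean,
              meas_error_sd, practice_gain, practice_loading,
              initial_state_sd_scale)
    if (!all(is.finite(vals))) stop("dynamic_spec fields must be finite")
    if (length(diffusion_sd) != 4L || any(diffusion_sd < 0)) {
      stop("diffusion_sd must be a nonnegative 4-vector")
    }
    if (length(manifest_mean) != 4L) stop("manifest_mean must have length 4")
    if (length(practice_loading) != 4L) {
      stop("practice_loading must have length 4")
    }
    if (meas_error_sd < 0) stop("meas_error_sd must be nonnegative")
    if (initial_state_sd_scale < 0) {
      stop("initial_state_sd_scale must be nonnegative")
    }
    if (!is_valid_corr(diffusion_corr)) {
      stop("diffusion_corr must be a symmetric positive semi-definite ",
           "correlation matrix with unit diagonal")
    }
    if (drift_trial >= 0) {
      warning("drift_trial >= 0: stationary-limit formulas (baseline latent ",
              "covariance) are undefined", call. = FALSE)
    }
  })
  invisible(spec)
}

#' @export
print.dynamic_spec <- function(x, ...) {
  cat("Continuous-time practice-effect dynamic specification\n")
  cat(sprintf("  trial self-feedback    %8.3f /yr\n", x$drift_trial))
  cat(sprintf("  practice self-feedback %8.3f /yr\n", x$drift_practice))
  cat(sprintf("  practice gain          %8.3f words/occasion\n",
              x$practice_gain))
  cat(sprintf("  manifest means         %s words\n",
              paste(sprintf("%.2f", x$manifest_mean), collapse = " ")))
  cat(sprintf("  diffusion sd           %s\n",
              paste(sprintf("%.2f", x$diffusion_sd), collapse = " ")))
  cat(sprintf("  measurement error sd   %8.3f words\n", x$meas_error_sd))
  invisible(x)
}

# drift and diffusion matrices of the stacked 5-state system
# (4 trial deviations + practice level; practice carries no diffusion)
drift_matrix <- function(spec) {
  diag(c(rep(spec$drift_trial, 4), spec$drift_practice))
}

diffusion_matrix <- function(spec) {
  Qc <- diag(spec$diffusion_sd) %*% spec$diffusion_corr %*%
    diag(spec$diffusion_sd)
  out <- matrix(0, 5, 5)
  out[1:4, 1:4] <- Qc
  out
}

# stationary covariance of the trial-deviation block; requires negative drift
stationary_cov_trials <- function(spec) {
  if (spec$drift_trial >= 0) {
    stop("stationary covariance requires drift_trial < 0", call. = FALSE)
  }
  Qc <- diag(spec$diffusion_sd) %*% spec$diffusion_corr %*%
    diag(spec$diffusion_sd)
  Qc / (-2 * spec$drift_trial)
}

validate_schedule <- function(times) {
  if (length(times) < 1L || !all(is.finite(times))) {
    stop("occasion schedule must be a nonempty finite vector")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("occasion schedule must be strictly increasing")
  }
  invisible(times)
}

#' Exact discrete-time translation of the continuous-time dynamics
#'
#' Translates a linear stochastic differential equation observed at a time
#' step `dt` into its exact discrete-time autoregression and innovation
#' variance. For a scalar process with drift `a` and diffusion variance `q`
#' the autoregression is `exp(a dt)` and the innovation variance
#' `q (exp(2 a dt) - 1) / (2 a)`, with the continuous limit `q dt` used when
#' `|a|` falls below `tol` to avoid 0/0.
#'
#' @param drift scalar drift rate (per year).
#' @param diffusion_var scalar diffusion variance rate.
#' @param dt positive time step in years.
#' @param tol threshold below which the zero-drift series limit is used.
#' @return list with elements `autoregression` and `innovation_var`.
#' @examples
#' discretize(0, 1, 0.5)           # zero-drift limit: (1, 0.5)
#' discretize(-3.471, 0, 1)$autoregression  # exp(-3.471)
#' @export
discretize <- function(drift, diffusion_var, dt, tol = 1e-8) {
  if (!is.finite(drift) || !is.finite(diffusion_var) || !is.finite(dt)) {
    stop("discretize() requires finite inputs")
  }
  if (dt <= 0) stop("dt must be positive")
  if (diffusion_var < 0) stop("diffusion_var must be nonnegative")
  ar <- exp(drift * dt)
  iv <- if (abs(drift) < tol) {
    diffusion_var * dt
  } else {
    diffusion_var * (exp(2 * drift * dt) - 1) / (2 * drift)
  }
  list(autoregression = ar, innovation_var = iv)
}

#' Matrix-exponential discretization of the full latent system
#'
#' Generalizes [discretize()] to a multivariate linear SDE with drift matrix
#' `A` and diffusion matrix `Q`: the state transition over `dt` is
#' `expm(A dt)` and the integrated process noise is obtained from the
#' augmented-matrix (Van Loan) exponential, equivalent to solving the
#' differential Lyapunov equation.
#'
#' @param A square drift matrix.
#' @param Q symmetric positive semi-definite diffusion matrix.
#' @param dt positive time step in years.
#' @return list with `transition` (matrix exponential) and `noise_cov`
#'   (integrated diffusion covariance).
#' @examples
#' d <- discretize_matrix(diag(c(-1, -2)), diag(c(2, 3)), 0.5)
#' d$transition
#' @export
discretize_matrix <- function(A, Q, dt) {
  stopifnot(is_square_matrix(A), is_square_matrix(Q), nrow(A) == nrow(Q))
  if (!all(is.finite(A)) || !all(is.finite(Q))) {
    stop("discretize_matrix() requires finite inputs")
  }
  if (dt <= 0) stop("dt must be positive")
  n <- nrow(A)
  M <- rbind(cbind(-A, Q), cbind(matrix(0, n, n), t(A))) * dt
  E <- as.matrix(Matrix::expm(M))
  F2 <- E[(n + 1):(2 * n), (n + 1):(2 * n), drop = FALSE]
  G1 <- E[1:n, (n + 1):(2 * n), drop = FALSE]
  Phi <- t(F2)
  Qd <- Phi %*% G1
  list(transition = Phi, noise_cov = (Qd + t(Qd)) / 2)
}

#' Expected practice level at each occasion
#'
#' The practice process starts at zero, receives the increment
#' `practice_gain` at the end of each occasion, and evolves between
#' occasions at rate `drift_practice`:
#' `level(k) = exp(drift_practice * dt_k) * (level(k-1) + practice_gain)`.
#' The returned value per occasion is the pre-increment level entering that
#' occasion's observation, so baseline observations are unaffected by
#' practice.
#'
#' @param practice_gain increment in words per occasion.
#' @param drift_practice practice self-feedback rate (per year).
#' @param times strictly increasing occasion times in years.
#' @return numeric vector of expected pre-increment practice levels (words).
#' @examples
#' practice_expectation(0.4, 0, c(0, 1, 2, 3))  # 0, 0.4, 0.8, 1.2
#' @export
practice_expectation <- function(practice_gain, drift_practice, times) {
  validate_schedule(times)
  K <- length(times)
  lev <- numeric(K)
  if (K > 1L) {
    for (k in 2:K) {
      dt <- times[k] - times[k - 1L]
      lev[k] <- exp(drift_practice * dt) * (lev[k - 1L] + practice_gain)
    }
  }
  lev
}

# per-unit-gain accumulation factors g_k (pre-increment level per word of
# gain); linear in practice_gain, used throughout the hierarchy
practice_unit_levels <- function(drift_practice, times) {
  practice_expectation(1, drift_practice, times)
}

# practice level on an arbitrary grid. Each end-of-occasion increment is
# rendered at the time of the occasion where it first affects an
# observation: the curve is flat (at the evolving current level) between
# occasions and jumps AT each occasion time, so the value over
# (t_k, t_{k+1}) is the evolved pre-increment level of occasion k and the
# value at t_k itself equals practice_expectation()'s occasion-k level.
practice_level_grid <- function(practice_gain, drift_practice, times, grid) {
  lev <- practice_expectation(practice_gain, drift_practice, times)
  K <- length(times)
  vapply(grid, function(t) {
    k <- findInterval(t, times)        # occasions with time <= t
    if (k == 0L) return(0)
    if (k < K || t == times[k]) {
      return(exp(drift_practice * (t - times[k])) * lev[k])
    }
    # beyond the final occasion the last increment has been applied
    exp(drift_practice * (t - times[K])) * (lev[K] + practice_gain)
  }, numeric(1))
}

#' Model-implied expected score trajectories
#'
#' Evaluates the expected observed score for each trial over a time grid,
#' under a given occasion schedule. Expected scores equal the manifest mean
#' plus the practice level mapped through the trial's practice loading; the
#' curves are flat before the first post-baseline increment and jump at each
#' occasion (the occasion's own observation uses the pre-increment level).
#'
#' @param spec a [dynamic_spec()].
#' @param times occasion schedule (years, strictly increasing).
#' @param grid evaluation grid covering `[0, max(times)]` (or beyond).
#' @return a tidy `data.frame` with columns `trial` (1-4), `time` and
#'   `expected_score`.
#' @export
trajectory_expectation <- function(spec, times, grid) {
  validate_schedule(times)
  if (length(grid) == 0L) stop("grid must be nonempty")
  lev <- practice_level_grid(spec$practice_gain, spec$drift_practice,
                             times, grid)
  out <- do.call(rbind, lapply(1:4, function(m) {
    data.frame(
      trial = m,
      time = grid,
      expected_score = spec$manifest_mean[m] + spec$practice_loading[m] * lev
    )
  }))
  rownames(out) <- NULL
  out
}

#' Simulate one subject's observed scores
#'
#' Draws a baseline latent state from the (scaled) stationary trial
#' covariance, propagates the trial deviations across occasions with the
#' exact discrete-time transition and correlated innovations, accumulates
#' the deterministic practice increments after each observation, and adds
#' measurement error.
#'
#' @param spec a [dynamic_spec()]; `drift_trial` must be negative.
#' @param times occasion schedule in years.
#' @param seed optional integer; identical seeds give identical scores and
#'   the caller's RNG stream is untouched. When `NULL` the current RNG
#'   stream is consumed.
#' @param integer_scores clip and round scores to the 0-12 word-list range
#'   (off by default, keeping the generative model Gaussian).
#' @return a 4 x K score matrix with rownames `trial1..trial4`.
#' @export
simulate_subject <- function(spec, times, seed = NULL,
                             integer_scores = FALSE) {
  validate_schedule(times)
  with_seed(seed, {
    scores <- simulate_subjects_matrix(spec, times, n = 1L,
                                       integer_scores = integer_scores)[, , 1L]
    matrix(scores, nrow = 4L, dimnames = list(paste0("trial", 1:4), NULL))
  })
}

# vectorized simulator: n independent subjects sharing one schedule.
# Returns a 4 x K x n array. Consumes the current RNG stream.
simulate_subjects_matrix <- function(spec, times, n, integer_scores = FALSE) {
  K <- length(times)
  Qinf <- stationary_cov_trials(spec)
  a <- spec$drift_trial
  s2 <- spec$initial_state_sd_scale^2
  lev <- practice_expectation(spec$practice_gain, spec$drift_practice, times)
  chol_or_zero <- function(S) {
    if (max(abs(S)) < 1e-14) matrix(0, nrow(S), nrow(S)) else chol(S)
  }
  x <- matrix(stats::rnorm(n * 4L), n, 4L) %*% chol_or_zero(s2 * Qinf)
  out <- array(NA_real_, c(4L, K, n))
  for (k in seq_len(K)) {
    if (k > 1L) {
      dt <- times[k] - times[k - 1L]
      ar <- exp(a * dt)
      Qd <- Qinf * (1 - exp(2 * a * dt))
      x <- ar * x + matrix(stats::rnorm(n * 4L), n, 4L) %*% chol_or_zero(Qd)
    }
    eps <- matrix(stats::rnorm(n * 4L, sd = spec$meas_error_sd), n, 4L)
    yk <- sweep(x + eps, 2L,
                spec$manifest_mean + spec$practice_loading * lev[k], `+`)
    out[, k, ] <- t(yk)
  }
  if (integer_scores) out <- pmin(pmax(round(out), 0), 12)
  out
}
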