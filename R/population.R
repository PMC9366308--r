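# Population layer: parameter packing, covariate/diagnosis moderation,
# random effects and the marginal log-posterior.
#
# All population parameters live on an unconstrained scale (see
# transforms.R). A subject's unconstrained parameter vector is
# theta + B %*% design_row (+ random effects on the location subset); the
# natural-scale dynamic specification follows by applying the links.
# Because the default random-effect subset (the four manifest means and the
# practice gain) enters the observation mean linearly and the practice
# process carries no diffusion, the random effects are integrated out of the
# Gaussian likelihood exactly: marginally y_i ~ N(mu_i, Sigma_i + A D A'),
# where D is the random-effect covariance and A the per-subject loading of
# the random effects onto the observations.

core_param_names <- function(variant = c("standard", "reparametrized")) {
  variant <- match.arg(variant)
  c("sf_practice", "sf_trial",
    paste0("diffusion_t", 1:4), "meas_error", "practice_gain",
    mean_param_names(variant))
}

mean_param_names <- function(variant) {
  if (variant == "standard") paste0("trial_", 1:4)
  else c("baseline", "dev_t2", "dev_t3", "dev_t4")
}

# 4x4 map from the mean-parameter block to the per-trial manifest means
mean_map <- function(variant) {
  if (variant == "standard") diag(4)
  else cbind(1, rbind(0, diag(3)))
}

#' Model configuration for hierarchical MAP estimation
#'
#' @param covariate moderating covariate: `"none"` (diagnosis groups only)
#'   or one of `"age"`, `"sex"`, `"education"`. With `subgroup = "all"` the
#'   covariate enters together with its diagnosis interactions (sensitivity
#'   model); within a single diagnosis subgroup it enters alone.
#' @param subgroup `"all"` or one diagnosis group to restrict the fit to.
#' @param variant `"standard"` estimates absolute per-trial manifest means;
#'   `"reparametrized"` estimates a baseline level plus trial 2-4 deviations
#'   from it.
#' @param re_subset names of the location parameters carrying correlated
#'   random effects; defaults to the four mean parameters plus
#'   `practice_gain`. Only location parameters (means and practice gain) are
#'   eligible: these enter the observation mean linearly, which is what
#'   permits exact marginalization.
#' @param priors list of prior widths, see [default_priors()].
#' @param optim list of optimizer settings (`maxit`, `factr`).
#' @param seed_jitter_sd SD of the deterministic seed jitter applied to the
#'   initial parameter vector.
#' @return an object of class `pe_model_config`.
#' @export
model_config <- function(covariate = c("none", "age", "sex", "education"),
                         subgroup = c("all", "CU", "MCI", "DAT"),
                         variant = c("standard", "reparametrized"),
                         re_subset = NULL,
                         priors = default_priors(),
                         optim = list(maxit = 400L, factr = 1e8),
                         seed_jitter_sd = 0.01) {
  covariate <- match.arg(covariate)
  subgroup <- match.arg(subgroup)
  variant <- match.arg(variant)
  loc <- c(mean_param_names(variant), "practice_gain")
  if (is.null(re_subset)) re_subset <- loc
  if (!all(re_subset %in% loc)) {
    stop("re_subset must be a subset of the location parameters: ",
         paste(loc, collapse = ", "))
  }
  structure(
    list(covariate = covariate, subgroup = subgroup, variant = variant,
         re_subset = re_subset, priors = priors, optim = optim,
         seed_jitter_sd = seed_jitter_sd),
    class = "pe_model_config"
  )
}

#' Default prior widths
#'
#' Broad, weakly informative priors for population means (scores stay in
#' words) and tighter, zero-centred priors for covariate effects and
#' individual differences: manifest means N(9, 10^2) words, trial deviations
#' and the practice increment N(0, 5^2), trial self-feedback N(0, 2^2) on
#' the pre-transform scale, practice self-feedback N(0, 0.25^2) (with at
#' most four occasions the compounding rate of practice gains is weakly
#' identified, and rates beyond +-0.5/yr imply implausible growth or decay
#' of retest gains over a three-year window; see the vignette),
#' diffusion/measurement SDs N(0, 2^2) on the
#' unconstrained (softplus) scale, covariate effects N(0, 2^2),
#' random-effect SDs half-normal(1) on the natural scale, correlation
#' parameters N(0, 1) on the unconstrained scale.
#'
#' @return named list of prior scales.
#' @export
default_priors <- function() {
  list(mean_mu = 9, mean_sd = 10, dev_sd = 5, gain_sd = 5,
       sfp_sd = 0.25, sft_sd = 2, sd_sd = 2, b_sd = 2, re_sd_scale = 1,
       corr_sd = 1)
}

design_cols <- function(config) {
  if (config$subgroup == "all") {
    cols <- c("mci", "dat")
    if (config$covariate != "none") {
      cols <- c(cols, config$covariate,
                paste0(config$covariate, "_mci"),
                paste0(config$covariate, "_dat"))
    }
    cols
  } else {
    if (config$covariate == "none") character(0)
    else config$covariate
  }
}

# filter records by subgroup, standardize age/education at the sample means
# of the analyzed records (sex stays coded -1/+1), and build design rows
design_info <- function(records, config) {
  groups <- vapply(records, `[[`, character(1), "group")
  if (config$subgroup != "all") {
    keep <- groups == config$subgroup
    records <- records[keep]
    groups <- groups[keep]
  }
  if (length(records) < 2L) {
    stop("need at least 2 subjects after subgroup filtering")
  }
  cols <- design_cols(config)
  scale_info <- NULL
  covvals <- NULL
  if (config$covariate != "none") {
    raw <- vapply(records, `[[`, numeric(1), config$covariate)
    if (anyNA(raw)) stop("covariate '", config$covariate, "' has missing values")
    if (config$covariate == "sex") {
      covvals <- raw
      scale_info <- list(center = 0, scale = 1)
    } else {
      scale_info <- list(center = mean(raw), scale = stats::sd(raw))
      covvals <- (raw - scale_info$center) / scale_info$scale
    }
  }
  D <- matrix(0, length(records), length(cols),
              dimnames = list(NULL, cols))
  if (config$subgroup == "all") {
    D[, "mci"] <- as.numeric(groups == "MCI")
    D[, "dat"] <- as.numeric(groups == "DAT")
    if (config$covariate != "none") {
      D[, config$covariate] <- covvals
      D[, paste0(config$covariate, "_mci")] <- covvals * D[, "mci"]
      D[, paste0(config$covariate, "_dat")] <- covvals * D[, "dat"]
    }
  } else if (length(cols) > 0L) {
    D[, cols[1L]] <- covvals
  }
  list(records = records, design = D, cols = cols, scale_info = scale_info)
}

# parameter-vector layout bookkeeping
make_parinfo <- function(config, cols) {
  pn <- core_param_names(config$variant)
  mn <- mean_param_names(config$variant)
  r <- length(config$re_subset)
  nm <- c(paste0("t:", pn))
  if (length(cols) > 0L) {
    nm <- c(nm, as.vector(outer(pn, cols, function(p, c)
      paste0("b:", p, ":", c))))
  }
  nm <- c(nm, paste0("dc:", seq_len(6)))
  if (r > 0L) {
    nm <- c(nm, paste0("rs:", config$re_subset))
    if (r > 1L) nm <- c(nm, paste0("rc:", seq_len(r * (r - 1) / 2)))
  }
  idx <- seq_along(nm)
  names(idx) <- nm
  list(
    names = nm, n = length(nm), param_names = pn, mean_names = mn,
    cols = cols, re_subset = config$re_subset, variant = config$variant,
    theta_idx = stats::setNames(idx[paste0("t:", pn)], pn),
    b_idx = if (length(cols) > 0L) {
      matrix(idx[as.vector(outer(pn, cols, function(p, c)
        paste0("b:", p, ":", c)))], nrow = length(pn),
        dimnames = list(pn, cols))
    } else matrix(integer(0), nrow = length(pn), ncol = 0,
                  dimnames = list(pn, NULL)),
    dc_idx = idx[paste0("dc:", seq_len(6))],
    rs_idx = if (r > 0L) {
      stats::setNames(idx[paste0("rs:", config$re_subset)], config$re_subset)
    } else integer(0),
    rc_idx = if (r > 1L) idx[paste0("rc:", seq_len(r * (r - 1) / 2))]
             else integer(0)
  )
}

unpack_par <- function(par, pinfo) {
  theta <- stats::setNames(par[pinfo$theta_idx], pinfo$param_names)
  B <- matrix(par[pinfo$b_idx], nrow = length(pinfo$param_names),
              dimnames = dimnames(pinfo$b_idx))
  r <- length(pinfo$re_subset)
  Rre <- if (r > 1L) corr_from_unconstrained(par[pinfo$rc_idx], r)
         else diag(max(r, 1L))[seq_len(r), seq_len(r), drop = FALSE]
  list(
    theta = theta, B = B,
    Rdiff = corr_from_unconstrained(par[pinfo$dc_idx], 4L),
    re_sd = if (r > 0L) softplus(par[pinfo$rs_idx]) else numeric(0),
    Rre = Rre
  )
}

#' Resolve a subject-level dynamic specification
#'
#' Builds the natural-scale [dynamic_spec()] implied by a population model
#' for one subject: unconstrained subject vector
#' `theta + B %*% design_row + u` on the random-effect subset, then
#' transformed to the natural scale.
#'
#' @param pop list with `theta` (named unconstrained population means), `B`
#'   (covariate-effect matrix, rows = parameters), `diffusion_corr` (natural
#'   correlation matrix), `variant`, and `re_subset`.
#' @param design_row numeric design vector (zero-length for no covariates).
#' @param u random-effect vector aligned with `pop$re_subset` (default zero).
#' @return a [dynamic_spec()].
#' @export
subject_spec <- function(pop, design_row = numeric(0), u = NULL) {
  pn <- names(pop$theta)
  stopifnot(!is.null(pn), setequal(pn, core_param_names(pop$variant)))
  v <- pop$theta
  if (length(design_row) > 0L) {
    if (ncol(pop$B) != length(design_row)) {
      stop("design_row length does not match the covariate-effect matrix")
    }
    v <- v + drop(pop$B %*% design_row)
  }
  if (!is.null(u)) {
    if (length(u) != length(pop$re_subset)) {
      stop("random-effect vector does not match re_subset")
    }
    v[pop$re_subset] <- v[pop$re_subset] + u
  }
  nat <- natural_from_unconstrained(v)
  mn <- mean_param_names(pop$variant)
  dynamic_spec(
    drift_trial = nat[["sf_trial"]],
    drift_practice = nat[["sf_practice"]],
    diffusion_sd = nat[paste0("diffusion_t", 1:4)],
    diffusion_corr = pop$diffusion_corr,
    manifest_mean = drop(mean_map(pop$variant) %*% nat[mn]),
    meas_error_sd = nat[["meas_error"]],
    practice_gain = nat[["practice_gain"]]
  )
}

# --- prepared data -----------------------------------------------------

# precompute per-subject index structures so the objective is cheap
prepare_data <- function(records, config) {
  di <- design_info(records, config)
  pinfo <- make_parinfo(config, di$cols)
  M <- mean_map(config$variant)
  r <- length(config$re_subset)
  mean_re <- match(config$re_subset, mean_param_names(config$variant))
  pe_col <- match("practice_gain", config$re_subset)  # NA when absent
  subs <- lapply(seq_along(di$records), function(i) {
    rec <- di$records[[i]]
    K <- length(rec$times)
    y <- as.vector(rec$scores)          # occasion-major
    obs <- which(!is.na(y))
    ti <- rep(1:4, K)[obs]
    oi <- rep(seq_len(K), each = 4L)[obs]
    nobs <- length(obs)
    # linear-index matrices into the 4x4 stationary block and the KxK
    # occasion-decay factor matrix
    idxQ <- matrix(ti[rep(seq_len(nobs), nobs)] +
                     4L * (ti[rep(seq_len(nobs), each = nobs)] - 1L),
                   nobs, nobs)
    idxC <- matrix(oi[rep(seq_len(nobs), nobs)] +
                     K * (oi[rep(seq_len(nobs), each = nobs)] - 1L),
                   nobs, nobs)
    Afixed <- NULL
    if (r > 0L) {
      Afixed <- matrix(0, nobs, r)
      for (j in seq_len(r)) {
        if (!is.na(mean_re[j])) Afixed[, j] <- M[ti, mean_re[j]]
      }
    }
    list(
      y = y[obs], obs = obs, times = rec$times, K = K, nobs = nobs,
      trial_idx = ti, occ_idx = oi, idxQ = idxQ, idxC = idxC,
      Afixed = Afixed, pe_col = pe_col,
      diag_idx = seq(1L, nobs * nobs, by = nobs + 1L),
      d = di$design[i, ], key = paste(signif(di$design[i, ], 12),
                                      collapse = "|")
    )
  })
  list(subjects = subs, design = di$design, cols = di$cols,
       scale_info = di$scale_info, records = di$records,
       config = config, pinfo = pinfo)
}

# --- marginal likelihood -----------------------------------------------

# natural parameters for one design row (subject-shared quantities)
resolve_nat <- function(up, pinfo, d) {
  v <- up$theta
  if (length(d) > 0L) v <- v + drop(up$B %*% d)
  nat <- natural_from_unconstrained(v)
  sds <- nat[paste0("diffusion_t", 1:4)]
  a <- nat[["sf_trial"]]
  Qinf <- (sds %o% sds) * up$Rdiff / (-2 * a)
  list(
    a = a, b = nat[["sf_practice"]],
    means = drop(mean_map(pinfo$variant) %*% nat[pinfo$mean_names]),
    gain = nat[["practice_gain"]],
    r2 = nat[["meas_error"]]^2 + .var_floor,
    Qinf = Qinf
  )
}

# log marginal likelihood of all subjects given an unpacked parameter set;
# optionally returns per-subject solves for the analytic location gradient
marginal_loglik <- function(up, prep, want_grad_parts = FALSE) {
  pinfo <- prep$pinfo
  r <- length(pinfo$re_subset)
  D <- if (r > 0L) (up$re_sd %o% up$re_sd) * up$Rre else NULL
  natcache <- list()
  ll <- 0
  log2pi <- log(2 * pi)
  parts <- if (want_grad_parts) vector("list", length(prep$subjects))
  for (i in seq_along(prep$subjects)) {
    s <- prep$subjects[[i]]
    nat <- natcache[[s$key]]
    if (is.null(nat)) {
      nat <- resolve_nat(up, pinfo, s$d)
      natcache[[s$key]] <- nat
    }
    # occasion decay factors exp(a |t_k - t_j|) via the monotone exp(a t)
    ea <- exp(nat$a * s$times)
    Ck <- matrix(ea, s$K, s$K)
    Cmat <- pmin.int(Ck, t(Ck)) / pmax.int(Ck, t(Ck))
    sigma <- nat$Qinf[s$idxQ] * Cmat[s$idxC]
    dim(sigma) <- c(s$nobs, s$nobs)
    sigma[s$diag_idx] <- sigma[s$diag_idx] + nat$r2
    # pre-increment practice accumulation per unit gain
    g <- numeric(s$K)
    if (s$K > 1L) {
      for (k in 2:s$K) {
        g[k] <- exp(nat$b * (s$times[k] - s$times[k - 1L])) * (g[k - 1L] + 1)
      }
    }
    mu <- nat$means[s$trial_idx] + g[s$occ_idx] * nat$gain
    A <- NULL
    if (r > 0L) {
      A <- s$Afixed
      if (!is.na(s$pe_col)) A[, s$pe_col] <- g[s$occ_idx]
      sigma <- sigma + A %*% D %*% t(A)
    }
    resid <- s$y - mu
    ch <- tryCatch(chol(sigma), error = function(e) {
      stop(sprintf("marginal covariance not positive definite (subject %d)",
                   i), call. = FALSE)
    })
    z <- backsolve(ch, resid, transpose = TRUE)
    ll <- ll - 0.5 * s$nobs * log2pi - sum(log(diag(ch))) - 0.5 * sum(z^2)
    if (want_grad_parts) {
      parts[[i]] <- list(w = backsolve(ch, z), g = g, ch = ch,
                         resid = resid, A = A)  # w = sigma^{-1} resid
    }
  }
  if (want_grad_parts) list(ll = ll, parts = parts) else ll
}

# --- priors ------------------------------------------------------------

theta_prior_params <- function(pinfo, priors) {
  pn <- pinfo$param_names
  mu <- stats::setNames(numeric(length(pn)), pn)
  sd <- stats::setNames(numeric(length(pn)), pn)
  for (p in pn) {
    if (p %in% c("trial_1", "trial_2", "trial_3", "trial_4", "baseline")) {
      mu[p] <- priors$mean_mu; sd[p] <- priors$mean_sd
    } else if (grepl("^dev_t", p)) {
      sd[p] <- priors$dev_sd
    } else if (p == "practice_gain") {
      sd[p] <- priors$gain_sd
    } else if (p == "sf_practice") {
      sd[p] <- priors$sfp_sd
    } else if (p == "sf_trial") {
      sd[p] <- priors$sft_sd
    } else {
      sd[p] <- priors$sd_sd   # diffusion and measurement SDs, softplus scale
    }
  }
  list(mu = mu, sd = sd)
}

log_prior <- function(par, pinfo, priors) {
  tp <- theta_prior_params(pinfo, priors)
  lp <- sum(stats::dnorm(par[pinfo$theta_idx], tp$mu, tp$sd, log = TRUE))
  if (length(pinfo$b_idx) > 0L) {
    lp <- lp + sum(stats::dnorm(par[pinfo$b_idx], 0, priors$b_sd, log = TRUE))
  }
  lp <- lp + sum(stats::dnorm(par[pinfo$dc_idx], 0, priors$corr_sd,
                              log = TRUE))
  if (length(pinfo$rs_idx) > 0L) {
    u <- par[pinfo$rs_idx]
    sdnat <- softplus(u)
    # half-normal on the natural SD plus the softplus Jacobian
    lp <- lp + sum(log(2) + stats::dnorm(sdnat, 0, priors$re_sd_scale,
                                         log = TRUE) +
                     log(softplus_deriv(u)))
  }
  if (length(pinfo$rc_idx) > 0L) {
    lp <- lp + sum(stats::dnorm(par[pinfo$rc_idx], 0, priors$corr_sd,
                                log = TRUE))
  }
  lp
}

#' Log-posterior of the population model
#'
#' Marginal data log-likelihood (random effects integrated out exactly; see
#' the package vignette) plus log-priors on population means, covariate
#' effects, correlation parameters and random-effect SDs. Higher is better.
#' With zero subjects the value reduces to the prior density at the
#' evaluated point.
#'
#' @param par unconstrained parameter vector (see [fit_map()] for layout),
#'   or a fit object's `par`.
#' @param records list of subject records.
#' @param config a [model_config()].
#' @return scalar log-posterior in nats.
#' @export
log_posterior <- function(par, records, config = model_config()) {
  prep <- prepare_data(records, config)
  if (length(par) != prep$pinfo$n) {
    stop(sprintf("expected %d parameters, got %d", prep$pinfo$n,
                 length(par)))
  }
  marginal_loglik(unpack_par(par, prep$pinfo), prep) +
    log_prior(par, prep$pinfo, config$priors)
}

neg_log_post <- function(par, prep) {
  val <- tryCatch(
    marginal_loglik(unpack_par(par, prep$pinfo), prep) +
      log_prior(par, prep$pinfo, prep$config$priors),
    error = function(e) -Inf
  )
  if (!is.finite(val)) return(1e10)
  -val
}

# indices of location parameters (means + practice gain and their covariate
# effects): likelihood gradient available in closed form
location_idx <- function(pinfo) {
  loc_params <- c(pinfo$mean_names, "practice_gain")
  th <- pinfo$theta_idx[loc_params]
  bb <- if (length(pinfo$cols) > 0L) {
    as.vector(pinfo$b_idx[loc_params, , drop = FALSE])
  } else integer(0)
  sort(c(th, bb))
}

# hybrid gradient of the negative log-posterior: analytic for the location
# block, central finite differences elsewhere
neg_log_post_grad <- function(par, prep, h = 1e-5) {
  pinfo <- prep$pinfo
  up <- unpack_par(par, pinfo)
  res <- marginal_loglik(up, prep, want_grad_parts = TRUE)
  grad <- numeric(pinfo$n)

  loc_params <- c(pinfo$mean_names, "practice_gain")
  M <- mean_map(pinfo$variant)
  nloc <- length(loc_params)
  acc_theta <- stats::setNames(numeric(nloc), loc_params)
  acc_B <- matrix(0, nloc, length(pinfo$cols),
                  dimnames = list(loc_params, pinfo$cols))
  for (i in seq_along(prep$subjects)) {
    s <- prep$subjects[[i]]
    p <- res$parts[[i]]
    # d mu / d (location param): mean params load via mean_map columns,
    # practice_gain via the accumulation factors g
    Aloc <- cbind(M[s$trial_idx, , drop = FALSE], p$g[s$occ_idx])
    wA <- drop(crossprod(Aloc, p$w))
    acc_theta <- acc_theta + wA
    if (length(pinfo$cols) > 0L) {
      acc_B <- acc_B + wA %o% s$d
    }
  }
  tp <- theta_prior_params(pinfo, prep$config$priors)
  for (j in seq_len(nloc)) {
    pidx <- pinfo$theta_idx[loc_params[j]]
    grad[pidx] <- -(acc_theta[j] -
      (par[pidx] - tp$mu[loc_params[j]]) / tp$sd[loc_params[j]]^2)
  }
  if (length(pinfo$cols) > 0L) {
    for (j in seq_len(nloc)) {
      for (c in seq_along(pinfo$cols)) {
        pidx <- pinfo$b_idx[loc_params[j], c]
        grad[pidx] <- -(acc_B[j, c] -
          par[pidx] / prep$config$priors$b_sd^2)
      }
    }
  }
  loc <- location_idx(pinfo)
  for (j in setdiff(seq_len(pinfo$n), loc)) {
    pp <- par; pm <- par
    pp[j] <- pp[j] + h
    pm[j] <- pm[j] - h
    grad[j] <- (neg_log_post(pp, prep) - neg_log_post(pm, prep)) / (2 * h)
  }
  grad
}
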