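#' Hierarchical MAP estimation of the practice-effect model
#'
#' Optimizes the marginal log-posterior (random effects integrated out
#' exactly, see the package vignette) with L-BFGS from a deterministic,
#' seed-jittered initialization. Refitting with the same records and seed
#' reproduces the estimates to optimizer tolerance.
#'
#' @param records list of [subject_record()] objects.
#' @param config a [model_config()].
#' @param seed integer seed controlling the initialization jitter.
#' @return an object of class `pe_fit` with the parameter vector at the
#'   mode (`par`), natural-scale population estimates (`theta_natural`,
#'   `B_hat`, `re_sd`, `re_corr`, `diffusion_corr`), convergence metadata
#'   and the prepared data needed for summaries.
#' @export
fit_map <- function(records, config = model_config(), seed = 1) {
  prep <- prepare_data(records, config)
  pinfo <- prep$pinfo
  par0 <- initial_par(prep)
  par0 <- with_seed(seed, par0 + stats::rnorm(length(par0), 0,
                                              config$seed_jitter_sd))
  names(par0) <- pinfo$names
  obj0 <- neg_log_post(par0, prep)
  t0 <- proc.time()[["elapsed"]]
  opt <- stats::optim(
    par0, fn = neg_log_post, gr = neg_log_post_grad, prep = prep,
    method = "L-BFGS-B",
    control = list(maxit = config$optim$maxit %||% 400L,
                   factr = config$optim$factr %||% 1e8)
  )
  elapsed <- proc.time()[["elapsed"]] - t0
  gnorm <- sqrt(sum(neg_log_post_grad(opt$par, prep)^2))
  converged <- opt$convergence == 0L && is.finite(opt$value)
  if (!converged) {
    warning("MAP optimization did not converge (code ", opt$convergence,
            "): ", opt$message %||% "", call. = FALSE)
  }
  up <- unpack_par(opt$par, pinfo)
  theta_nat <- natural_from_unconstrained(up$theta)
  structure(
    list(
      par = opt$par, value = -opt$value, value_init = -obj0,
      theta_hat = up$theta, theta_natural = theta_nat,
      B_hat = up$B, re_sd = up$re_sd, re_corr = up$Rre,
      diffusion_corr = up$Rdiff,
      convergence = list(converged = converged, code = opt$convergence,
                         message = opt$message,
                         iterations = opt$counts[["function"]],
                         gradient_norm = gnorm, seconds = elapsed),
      config = config, seed = seed, prep = prep, vcov = NULL,
      cache = new.env(parent = emptyenv())
    ),
    class = "pe_fit"
  )
}

# deterministic data-driven starting values
initial_par <- function(prep) {
  pinfo <- prep$pinfo
  par <- numeric(pinfo$n)
  names(par) <- pinfo$names
  tm <- vapply(1:4, function(m) {
    vals <- unlist(lapply(prep$subjects, function(s) s$y[s$trial_idx == m]))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  if (pinfo$variant == "standard") {
    par[pinfo$theta_idx[paste0("trial_", 1:4)]] <- tm
  } else {
    par[pinfo$theta_idx["baseline"]] <- tm[1L]
    par[pinfo$theta_idx[c("dev_t2", "dev_t3", "dev_t4")]] <- tm[2:4] - tm[1L]
  }
  par[pinfo$theta_idx["practice_gain"]] <- 0.2
  par[pinfo$theta_idx["sf_practice"]] <- 0
  par[pinfo$theta_idx["sf_trial"]] <- softplus_inv(3)
  par[pinfo$theta_idx[paste0("diffusion_t", 1:4)]] <- softplus_inv(2)
  par[pinfo$theta_idx["meas_error"]] <- softplus_inv(0.5)
  if (length(pinfo$rs_idx) > 0L) par[pinfo$rs_idx] <- softplus_inv(1)
  par
}

#' @export
print.pe_fit <- function(x, ...) {
  cat(sprintf(
    "practice-effect model fit (%s%s, %s variant): %d subjects\n",
    if (x$config$covariate == "none") "diagnosis groups"
    else paste("sensitivity:", x$config$covariate),
    if (x$config$subgroup == "all") "" else paste0(", ", x$config$subgroup),
    x$config$variant, length(x$prep$subjects)
  ))
  cat(sprintf("  log-posterior %.2f, %s (|grad| %.3g, %d evaluations)\n",
              x$value,
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$gradient_norm, x$convergence$iterations))
  nat <- x$theta_natural
  cat(sprintf("  practice effect %.3f words/occasion, trial means %s\n",
              nat[["practice_gain"]],
              paste(sprintf("%.2f",
                drop(mean_map(x$config$variant) %*%
                       nat[mean_param_names(x$config$variant)])),
                collapse = " ")))
  invisible(x)
}

# finite-difference Hessian of the negative log-posterior at the mode;
# cached on the fit so repeated summaries are cheap
fit_vcov <- function(fit, ridge = 0) {
  if (!is.null(fit$vcov)) return(fit$vcov)
  if (!is.null(fit$cache$vcov)) return(fit$cache$vcov)
  H <- pracma::hessian(function(p) neg_log_post(p, fit$prep), fit$par)
  H <- (H + t(H)) / 2
  V <- tryCatch(solve(H + diag(ridge, nrow(H))), error = function(e) {
    stop("Gaussian approximation covariance is singular; retry with a ",
         "small ridge (e.g. summarize_fit(fit, ridge = 1e-6))",
         call. = FALSE)
  })
  V <- (V + t(V)) / 2
  if (!is.null(fit$cache)) fit$cache$vcov <- V
  V
}

#' Natural-scale parameter summary with credible intervals
#'
#' Draws from the Gaussian approximation to the posterior on the
#' unconstrained scale, transforms each draw to the natural scale, and
#' reports the mean, SD and 2.5%/97.5% quantiles for every population mean,
#' covariate effect, random-effect SD and correlation. Covariate effects on
#' constrained parameters are reported both on the estimation
#' (unconstrained) scale and as the natural-scale contrast
#' `transform(theta + b) - transform(theta)`. The `flag` column marks rows
#' whose 95% interval excludes zero with `"*"` and whose 90% interval
#' excludes zero with `"+"`.
#'
#' @param fit a [fit_map()] result.
#' @param n_draws number of Gaussian-approximation draws (>= 1000).
#' @param seed RNG seed for the draws.
#' @param ridge optional ridge added to the Hessian before inversion.
#' @return a `data.frame` with columns `parameter`, `mean`, `sd`, `ci2.5`,
#'   `ci97.5`, `flag`.
#' @export
summarize_fit <- function(fit, n_draws = 2000L, seed = 1, ridge = 0) {
  stopifnot(inherits(fit, "pe_fit"))
  if (n_draws < 1000L) stop("n_draws must be at least 1000")
  if (!fit$convergence$converged) {
    warning("summarizing a fit flagged as not converged", call. = FALSE)
  }
  V <- fit_vcov(fit, ridge = ridge)
  pinfo <- fit$prep$pinfo
  draws <- with_seed(seed, rmvnorm_chol(n_draws, fit$par, V))
  rows <- natural_rows(fit$par, pinfo)
  mat <- t(apply(draws, 1L, function(p) natural_rows(p, pinfo)$value))
  qs <- apply(mat, 2L, stats::quantile, probs = c(0.025, 0.05, 0.95, 0.975))
  excl0 <- function(lo, hi) (lo > 0 & hi > 0) | (lo < 0 & hi < 0)
  data.frame(
    parameter = rows$label,
    mean = colMeans(mat),
    sd = apply(mat, 2L, stats::sd),
    ci2.5 = qs[1L, ], ci97.5 = qs[4L, ],
    flag = ifelse(excl0(qs[1L, ], qs[4L, ]), "*",
                  ifelse(excl0(qs[2L, ], qs[3L, ]), "+", "")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# natural-scale report rows for one unconstrained parameter vector
natural_rows <- function(par, pinfo) {
  up <- unpack_par(par, pinfo)
  nat <- natural_from_unconstrained(up$theta)
  labels <- names(nat)
  values <- unname(nat)
  links <- param_links(pinfo$param_names)
  if (length(pinfo$cols) > 0L) {
    for (cc in pinfo$cols) {
      for (p in pinfo$param_names) {
        b <- up$B[p, cc]
        labels <- c(labels, paste0(cc, ":", p))
        values <- c(values, b)
        if (links[p] != "identity") {
          labels <- c(labels, paste0(cc, ":", p, ":natural"))
          values <- c(values, apply_link(up$theta[p] + b, links[p]) - nat[p])
        }
      }
    }
  }
  r <- length(pinfo$re_subset)
  if (r > 0L) {
    labels <- c(labels, paste0("re_sd:", pinfo$re_subset))
    values <- c(values, up$re_sd)
    if (r > 1L) {
      pairs <- which(lower.tri(up$Rre), arr.ind = TRUE)
      labels <- c(labels, sprintf("re_corr:%s-%s",
                                  pinfo$re_subset[pairs[, 1L]],
                                  pinfo$re_subset[pairs[, 2L]]))
      values <- c(values, up$Rre[pairs])
    }
  }
  dpairs <- which(lower.tri(up$Rdiff), arr.ind = TRUE)
  labels <- c(labels, sprintf("diffusion_corr:t%d-t%d",
                              dpairs[, 1L], dpairs[, 2L]))
  values <- c(values, up$Rdiff[dpairs])
  list(label = labels, value = values)
}

#' Posterior modes of the subject random effects
#'
#' Closed-form conditional means of the random-effect vectors given the
#' fitted population parameters (the best linear unbiased predictors of the
#' Gaussian hierarchy).
#'
#' @param fit a [fit_map()] result.
#' @return matrix with one row per subject and one column per random-effect
#'   parameter.
#' @export
random_effect_modes <- function(fit) {
  stopifnot(inherits(fit, "pe_fit"))
  prep <- fit$prep
  pinfo <- prep$pinfo
  r <- length(pinfo$re_subset)
  if (r == 0L) {
    return(matrix(numeric(0), length(prep$subjects), 0L))
  }
  up <- unpack_par(fit$par, pinfo)
  D <- (up$re_sd %o% up$re_sd) * up$Rre
  res <- marginal_loglik(up, prep, want_grad_parts = TRUE)
  out <- t(vapply(seq_along(prep$subjects), function(i) {
    p <- res$parts[[i]]
    drop(D %*% crossprod(p$A, p$w))   # D A' (Sigma + A D A')^{-1} resid
  }, numeric(r)))
  colnames(out) <- pinfo$re_subset
  rownames(out) <- vapply(prep$records, `[[`, character(1), "subject_id")
  out
}
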