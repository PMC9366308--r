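# shared fixtures: small specs and records built in code

unit_corr <- function(rho = 0.5, d = 4) {
  m <- matrix(rho, d, d)
  diag(m) <- 1
  m
}

test_spec <- function(...) {
  args <- utils::modifyList(list(
    drift_trial = -3.471, drift_practice = 0.009,
    diffusion_sd = c(3.795, 3.523, 2.781, 5.499),
    diffusion_corr = unit_corr(0.5),
    manifest_mean = c(6.087, 8.782, 9.837, 8.478),
    meas_error_sd = 0.299, practice_gain = 0.399
  ), list(...))
  do.call(dynamic_spec, args)
}

# a randomized small spec/record pair for property tests; all draws come
# from the caller's RNG stream
random_spec <- function() {
  z <- stats::rnorm(6, sd = 0.7)
  dynamic_spec(
    drift_trial = -stats::runif(1, 0.3, 5),
    drift_practice = stats::rnorm(1, 0, 0.4),
    diffusion_sd = stats::runif(4, 0.3, 5),
    diffusion_corr = corr_from_unconstrained(z, 4),
    manifest_mean = stats::runif(4, 3, 11),
    meas_error_sd = stats::runif(1, 0.05, 1.5),
    practice_gain = stats::rnorm(1, 0.4, 0.5),
    initial_state_sd_scale = stats::runif(1, 0.5, 1.5)
  )
}

random_record <- function(spec, max_occasions = 4L, missing_prob = 0.15) {
  K <- sample.int(max_occasions, 1L)
  times <- if (K == 1L) 0 else cumsum(c(0, stats::runif(K - 1L, 0.5, 1.6)))
  scores <- simulate_subject(spec, times)
  repeat {
    mask <- matrix(stats::runif(4 * K) < missing_prob, 4L, K)
    if (!all(mask)) break
  }
  scores[mask] <- NA
  subject_record("r1", times, scores, sample(c("CU", "MCI", "DAT"), 1L),
                 age = 72, sex = 1, education = 16)
}

# small, fast cohort for fitting tests: scaled-down group sizes and
# occasion counts, noise levels kept from the default configuration
small_cohort_config <- function(scale = 0.25) {
  cfg <- default_cohort_config()
  occ <- round(cfg$occasion_counts * scale)
  cfg$occasion_counts <- occ
  cfg$group_sizes <- rowSums(occ)
  names(cfg$group_sizes) <- rownames(occ)
  cfg
}

# pack a full parameter vector for a prepared dataset from natural-scale
# generating values (used to evaluate the posterior at known parameters)
pack_par <- function(prep, theta_nat, effects = list(), dcorr = unit_corr(0.5),
                     re_sd = NULL, re_corr = NULL) {
  pinfo <- prep$pinfo
  par <- numeric(pinfo$n)
  names(par) <- pinfo$names
  par[pinfo$theta_idx] <- ctpe:::unconstrained_from_natural(theta_nat)
  for (col in names(effects)) {
    e <- effects[[col]]
    for (nm in names(e)) par[pinfo$b_idx[nm, col]] <- e[nm]
  }
  par[pinfo$dc_idx] <- corr_to_unconstrained(dcorr)
  if (length(pinfo$rs_idx) > 0L) {
    par[pinfo$rs_idx] <- softplus_inv(re_sd)
    if (length(pinfo$rc_idx) > 0L) {
      par[pinfo$rc_idx] <- corr_to_unconstrained(re_corr)
    }
  }
  par
}

# one moderately sized noisy fit shared across test files (cached)
.fit_cache <- new.env(parent = emptyenv())

small_noisy_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    coh <- generate_cohort(small_cohort_config(0.12), seed = 21)
    .fit_cache$fit <- suppressWarnings(
      fit_map(coh, model_config(optim = list(maxit = 120, factr = 1e7)),
              seed = 2)
    )
  }
  .fit_cache$fit
}

# near-noise-free cohort and fit shared by recovery and overlay tests
near_noiseless_config <- function() {
  cfg <- small_cohort_config(0.12)
  cfg$generating$theta_natural[paste0("diffusion_t", 1:4)] <- 0.02
  cfg$generating$theta_natural["meas_error"] <- 0.02
  cfg$generating$re_sd[] <- 1e-3
  cfg$generating$mci_effects[] <- 0
  cfg$generating$dat_effects[] <- 0
  cfg
}

near_noiseless_fit <- function() {
  if (is.null(.fit_cache$nnf)) {
    coh <- generate_cohort(near_noiseless_config(), seed = 11)
    .fit_cache$nnf <- suppressWarnings(fit_map(
      coh, model_config(re_subset = character(0),
                        optim = list(maxit = 320, factr = 1e7)), seed = 1
    ))
  }
  .fit_cache$nnf
}
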