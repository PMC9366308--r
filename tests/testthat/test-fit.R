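# MAP estimation: recovery, determinism, shrinkage and summaries

test_that("manifest means are recovered on near-noise-free data", {
  fit <- near_noiseless_fit()
  gen <- near_noiseless_config()$generating$theta_natural
  for (m in paste0("trial_", 1:4)) {
    expect_lt(abs(fit$theta_natural[[m]] - gen[[m]]), 0.01)
  }
  expect_lt(abs(fit$theta_natural[["practice_gain"]] -
                  gen[["practice_gain"]]), 0.02)
  # no spurious diagnosis effects on the means
  expect_lt(max(abs(fit$B_hat[paste0("trial_", 1:4), ])), 0.05)
  expect_gte(fit$value, fit$value_init)
})

test_that("identical records and seed give identical estimates", {
  coh <- generate_cohort(small_cohort_config(0.08), seed = 13)
  cfg <- model_config(optim = list(maxit = 40L, factr = 1e9))
  f1 <- suppressWarnings(fit_map(coh, cfg, seed = 9))
  f2 <- suppressWarnings(fit_map(coh, cfg, seed = 9))
  expect_identical(f1$par, f2$par)
  # a different jitter seed moves the start but lands nearby
  f3 <- suppressWarnings(fit_map(coh, cfg, seed = 10))
  expect_false(identical(f1$par, f3$par))
})

test_that("the posterior is invariant to subject ordering", {
  coh <- generate_cohort(small_cohort_config(0.1), seed = 14)
  cfg <- model_config()
  prep1 <- ctpe:::prepare_data(coh, cfg)
  set.seed(77)
  perm <- sample(seq_along(coh))
  prep2 <- ctpe:::prepare_data(new_cohort <- coh[perm], cfg)
  par <- ctpe:::initial_par(prep1)
  expect_equal(ctpe:::neg_log_post(par, prep1),
               ctpe:::neg_log_post(par, prep2), tolerance = 1e-10)
})

test_that("tightening the random-effect hyperprior shrinks the RE SDs", {
  coh <- generate_cohort(small_cohort_config(0.12), seed = 15)
  loose <- default_priors()
  tight <- default_priors()
  tight$re_sd_scale <- 0.2
  f_loose <- suppressWarnings(fit_map(
    coh, model_config(priors = loose, optim = list(maxit = 80, factr = 1e8)),
    seed = 3
  ))
  f_tight <- suppressWarnings(fit_map(
    coh, model_config(priors = tight, optim = list(maxit = 80, factr = 1e8)),
    seed = 3
  ))
  expect_lt(sum(f_tight$re_sd), sum(f_loose$re_sd))
})

test_that("standard and reparametrized likelihoods agree at matched values", {
  coh <- generate_cohort(small_cohort_config(0.12), seed = 31)
  gen <- default_cohort_config()$generating
  prep_s <- ctpe:::prepare_data(coh, model_config(variant = "standard"))
  prep_r <- ctpe:::prepare_data(coh, model_config(variant = "reparametrized"))

  # map the mean block m -> (baseline, deviations) and the random-effect
  # covariance through the same linear map
  Mrep <- ctpe:::mean_map("reparametrized")
  L <- rbind(cbind(Mrep, 0), c(0, 0, 0, 0, 1))
  D_rep <- (gen$re_sd %o% gen$re_sd) * unname(gen$re_corr)
  D_std <- L %*% D_rep %*% t(L)
  sd_std <- sqrt(diag(D_std))
  corr_std <- D_std / (sd_std %o% sd_std)
  diag(corr_std) <- 1

  th_s <- gen$theta_natural
  th_r <- th_s
  names(th_r) <- sub("^trial_1$", "baseline", names(th_r))
  names(th_r) <- sub("^trial_([234])$", "dev_t\\1", names(th_r))
  m <- th_s[paste0("trial_", 1:4)]
  th_r[c("baseline", "dev_t2", "dev_t3", "dev_t4")] <-
    c(m[1], m[2] - m[1], m[3] - m[1], m[4] - m[1])

  map_eff <- function(e) {
    full <- stats::setNames(numeric(12), names(th_s))
    full[names(e)] <- e
    mm <- full[paste0("trial_", 1:4)]
    out <- full
    names(out) <- names(th_r)
    out[c("baseline", "dev_t2", "dev_t3", "dev_t4")] <-
      c(mm[1], mm[2] - mm[1], mm[3] - mm[1], mm[4] - mm[1])
    out[out != 0]
  }
  eff_s <- list(mci = gen$mci_effects, dat = gen$dat_effects)
  eff_r <- list(mci = map_eff(gen$mci_effects),
                dat = map_eff(gen$dat_effects))

  par_s <- pack_par(prep_s, th_s, eff_s, unname(gen$diffusion_corr),
                    sd_std, corr_std)
  par_r <- pack_par(prep_r, th_r, eff_r, unname(gen$diffusion_corr),
                    gen$re_sd, unname(gen$re_corr))
  ll_s <- ctpe:::marginal_loglik(ctpe:::unpack_par(par_s, prep_s$pinfo),
                                 prep_s)
  ll_r <- ctpe:::marginal_loglik(ctpe:::unpack_par(par_r, prep_r$pinfo),
                                 prep_r)
  expect_equal(ll_s, ll_r, tolerance = 1e-8)
})

test_that("summaries order intervals and match the Gaussian closed form", {
  fit <- small_noisy_fit()
  smry <- suppressWarnings(summarize_fit(fit, n_draws = 3000, seed = 5))
  expect_true(all(c("parameter", "mean", "sd", "ci2.5", "ci97.5", "flag")
                  %in% names(smry)))
  expect_true(all(smry$ci2.5 <= smry$mean + 1e-10))
  expect_true(all(smry$mean <= smry$ci97.5 + 1e-10))
  expect_true(all(c("sf_practice", "sf_trial", "practice_gain", "trial_1",
                    "mci:trial_1", "dat:trial_4", "re_sd:practice_gain",
                    "re_corr:trial_2-trial_1", "diffusion_corr:t2-t1")
                  %in% smry$parameter))
  # identity-transformed parameter: draws must reproduce the Gaussian
  # approximation quantiles
  j <- fit$prep$pinfo$theta_idx[["trial_1"]]
  V <- ctpe:::fit_vcov(fit)
  sdj <- sqrt(V[j, j])
  row <- smry[smry$parameter == "trial_1", ]
  expect_equal(row$mean, unname(fit$par[j]),
               tolerance = 4 * sdj / sqrt(3000))
  expect_equal(row$ci97.5, unname(fit$par[j]) + stats::qnorm(0.975) * sdj,
               tolerance = 10 * sdj / sqrt(3000))
})

test_that("a zero-variance approximation collapses intervals to the mode", {
  fit <- small_noisy_fit()
  fit0 <- fit
  fit0$vcov <- diag(1e-18, length(fit$par))
  smry <- suppressWarnings(summarize_fit(fit0, n_draws = 1000, seed = 6))
  expect_lt(max(smry$ci97.5 - smry$ci2.5), 1e-6)
  expect_equal(smry[smry$parameter == "practice_gain", "mean"],
               fit$theta_natural[["practice_gain"]], tolerance = 1e-6)
})

test_that("random-effect modes maximize the conditional posterior", {
  fit <- small_noisy_fit()
  modes <- random_effect_modes(fit)
  expect_equal(dim(modes), c(length(fit$prep$subjects), 5L))
  expect_true(all(is.finite(modes)))
  # direct numeric maximization for one subject must land on the BLUP
  i <- which(vapply(fit$prep$subjects, function(s) s$K, integer(1)) >= 3)[1]
  rec <- fit$prep$records[[i]]
  d <- fit$prep$subjects[[i]]$d
  up <- ctpe:::unpack_par(fit$par, fit$prep$pinfo)
  D <- (up$re_sd %o% up$re_sd) * up$Rre
  Dinv <- solve(D)
  pop <- list(theta = up$theta, B = up$B, diffusion_corr = up$Rdiff,
              variant = "standard", re_subset = fit$prep$pinfo$re_subset)
  negcond <- function(u) {
    uu <- stats::setNames(u, fit$prep$pinfo$re_subset)
    -(kalman_loglik(subject_spec(pop, d, uu), rec) -
        0.5 * drop(u %*% Dinv %*% u))
  }
  opt <- stats::optim(numeric(5), negcond, method = "BFGS",
                      control = list(reltol = 1e-12))
  expect_equal(unname(modes[i, ]), opt$par, tolerance = 1e-4)
})
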