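# population layer: subject resolution, priors, posterior and gradient

test_that("subject_spec resolves moderation on the unconstrained scale", {
  gen <- default_cohort_config()$generating
  theta_u <- ctpe:::unconstrained_from_natural(gen$theta_natural)
  B <- matrix(0, 12, 2, dimnames = list(names(theta_u), c("mci", "dat")))
  B["trial_1", "mci"] <- -1.423
  pop <- list(theta = theta_u, B = B, diffusion_corr = gen$diffusion_corr,
              variant = "standard", re_subset = names(gen$re_sd))
  # zero design and random effects: the population values themselves
  s0 <- subject_spec(pop, design_row = c(0, 0))
  expect_equal(s0$manifest_mean[1], 6.087, tolerance = 1e-10)
  expect_equal(s0$drift_trial, -3.471, tolerance = 1e-10)
  expect_equal(s0$practice_gain, 0.399, tolerance = 1e-10)
  # an MCI subject's Trial 1 mean: intercept plus diagnosis effect
  s1 <- subject_spec(pop, design_row = c(1, 0))
  expect_equal(s1$manifest_mean[1], 6.087 - 1.423, tolerance = 1e-10)
  # identity-scale random effect adds directly
  u <- stats::setNames(c(0.5, 0, 0, 0, -0.1), names(gen$re_sd))
  s2 <- subject_spec(pop, design_row = c(0, 0), u = u)
  expect_equal(s2$manifest_mean[1], 6.087 + 0.5, tolerance = 1e-10)
  expect_equal(s2$practice_gain, 0.399 - 0.1, tolerance = 1e-10)
  expect_error(subject_spec(pop, design_row = c(0, 0), u = u[1:3]),
               "re_subset")
})

test_that("log-posterior with no data equals the prior density", {
  cfg <- model_config()
  coh <- generate_cohort(small_cohort_config(0.08), seed = 2)
  prep <- ctpe:::prepare_data(coh, cfg)
  par <- ctpe:::initial_par(prep)
  lp <- ctpe:::log_prior(par, prep$pinfo, cfg$priors)
  # strip the subjects: the likelihood term vanishes
  prep0 <- prep
  prep0$subjects <- list()
  expect_equal(-ctpe:::neg_log_post(par, prep0), lp, tolerance = 1e-10)
  # doubling the dataset doubles the likelihood part only
  prep2 <- prep
  prep2$subjects <- c(prep$subjects, prep$subjects)
  l1 <- -ctpe:::neg_log_post(par, prep) - lp
  l2 <- -ctpe:::neg_log_post(par, prep2) - lp
  expect_equal(l2, 2 * l1, tolerance = 1e-8)
})

test_that("marginal likelihood without random effects matches the filter", {
  cfg <- model_config(re_subset = character(0))
  coh <- generate_cohort(small_cohort_config(0.1), seed = 3)
  prep <- ctpe:::prepare_data(coh, cfg)
  par <- ctpe:::initial_par(prep)
  set.seed(30)
  par <- par + stats::rnorm(length(par), 0, 0.05)
  up <- ctpe:::unpack_par(par, prep$pinfo)
  mll <- ctpe:::marginal_loglik(up, prep)
  resolver <- function(rec) {
    d <- c(as.numeric(rec$group == "MCI"), as.numeric(rec$group == "DAT"))
    subject_spec(list(theta = up$theta, B = up$B, diffusion_corr = up$Rdiff,
                      variant = "standard", re_subset = character(0)),
                 design_row = d)
  }
  expect_equal(mll, dataset_loglik(resolver, prep$records),
               tolerance = 1e-8)
})

test_that("analytic location gradient matches central finite differences", {
  cfg <- model_config()
  coh <- generate_cohort(small_cohort_config(0.1), seed = 4)
  prep <- ctpe:::prepare_data(coh, cfg)
  set.seed(44)
  par <- ctpe:::initial_par(prep) + stats::rnorm(prep$pinfo$n, 0, 0.05)
  g <- ctpe:::neg_log_post_grad(par, prep)
  loc <- ctpe:::location_idx(prep$pinfo)
  h <- 1e-5
  for (j in loc) {
    pp <- par; pm <- par
    pp[j] <- pp[j] + h
    pm[j] <- pm[j] - h
    fd <- (ctpe:::neg_log_post(pp, prep) -
             ctpe:::neg_log_post(pm, prep)) / (2 * h)
    expect_equal(g[j], fd, tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("marginal covariance equals the filter with an augmented state", {
  # one subject, random effect on practice gain only: integrating the
  # random effect equals averaging the conditional likelihood (quadrature)
  cfg <- model_config(re_subset = "practice_gain")
  gen <- default_cohort_config()$generating
  coh <- generate_cohort(small_cohort_config(0.08), seed = 6)
  prep <- ctpe:::prepare_data(coh, cfg)
  par <- ctpe:::initial_par(prep)
  up <- ctpe:::unpack_par(par, prep$pinfo)
  idx <- which(vapply(prep$subjects, function(s) s$K, integer(1)) >= 3)[1]
  sub <- prep$subjects[[idx]]
  prep1 <- prep
  prep1$subjects <- list(sub)
  mll <- ctpe:::marginal_loglik(up, prep1)
  # Gauss-Hermite integration over the scalar random effect
  gh_n <- 80
  # nodes/weights via eigen decomposition of the Jacobi matrix
  i <- seq_len(gh_n - 1)
  Jm <- matrix(0, gh_n, gh_n)
  Jm[cbind(i, i + 1)] <- sqrt(i / 2)
  Jm[cbind(i + 1, i)] <- sqrt(i / 2)
  ev <- eigen(Jm, symmetric = TRUE)
  nodes <- ev$values
  weights <- ev$vectors[1, ]^2 * sqrt(pi)
  sdre <- up$re_sd[1]
  rec <- prep$records[[idx]]
  cond <- vapply(nodes, function(z) {
    u <- stats::setNames(sqrt(2) * sdre * z, "practice_gain")
    spec <- subject_spec(list(theta = up$theta, B = up$B,
                              diffusion_corr = up$Rdiff,
                              variant = "standard",
                              re_subset = "practice_gain"),
                         design_row = sub$d, u = u)
    kalman_loglik(spec, rec)
  }, numeric(1))
  mx <- max(cond)
  quad <- mx + log(sum(weights / sqrt(pi) * exp(cond - mx)))
  expect_equal(mll, quad, tolerance = 1e-6)
})

test_that("model configs round-trip through YAML", {
  cfg <- model_config("age", "MCI", "reparametrized",
                      optim = list(maxit = 55L, factr = 1e7))
  f <- tempfile(fileext = ".yaml")
  write_model_config(cfg, f)
  back <- read_model_config(f)
  expect_equal(back$covariate, "age")
  expect_equal(back$subgroup, "MCI")
  expect_equal(back$variant, "reparametrized")
  expect_equal(back$optim$maxit, 55L)
  expect_equal(back$re_subset, cfg$re_subset)
})
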