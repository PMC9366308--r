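# synthetic-cohort generator: design fidelity and determinism

test_that("default configuration encodes the emulated study design", {
  cfg <- default_cohort_config()
  expect_equal(unname(cfg$group_sizes), c(126, 85, 45))
  expect_equal(unname(cfg$occasion_counts["CU", ]), c(20, 45, 40, 21))
  expect_equal(cfg$occasion_counts["DAT", "4"], 0)
  expect_equal(cfg$interval_mean, 1.09)
  expect_true(ctpe:::is_valid_corr(unname(cfg$generating$re_corr)))
  expect_error(validate_cohort_config({
    bad <- cfg
    bad$group_sizes["CU"] <- 10
    bad
  }), "sum")
})

test_that("generated cohorts honour sizes, schedules and determinism", {
  coh <- generate_cohort(default_cohort_config(), seed = 1)
  groups <- vapply(coh, `[[`, character(1), "group")
  expect_length(coh, 256L)
  expect_equal(sum(groups == "CU"), 126L)
  Ks <- vapply(coh, function(r) length(r$times), integer(1))
  expect_equal(sum(Ks == 4L & groups == "CU"), 21L)
  expect_equal(sum(Ks == 4L & groups == "DAT"), 0L)
  expect_true(all(vapply(coh, function(r) r$times[1] == 0, logical(1))))
  # identical seed, identical cohort (and byte-identical CSV)
  coh2 <- generate_cohort(default_cohort_config(), seed = 1)
  expect_identical(coh, coh2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, f1); write_cohort_csv(coh2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed gives different scores
  expect_false(identical(coh, generate_cohort(default_cohort_config(),
                                              seed = 2)))
})

test_that("covariate distributions track their configured values", {
  descs <- lapply(1:6, function(s) {
    cohort_descriptives(generate_cohort(default_cohort_config(), seed = s))
  })
  pw <- sapply(descs, function(d) d$pct_women)
  expect_true(all(abs(rowMeans(pw) - c(71, 67, 60)) < 6))
  ages <- sapply(descs, function(d) d$age_mean)
  expect_true(abs(mean(ages[1, ]) - 70.06) < 1.5)
  ints <- sapply(descs, function(d) d$mean_interval)
  expect_true(abs(mean(ints) - 1.09) < 0.03)
})

test_that("noise-free configuration reproduces the generating means", {
  cfg <- default_cohort_config()
  cfg$generating$theta_natural[paste0("diffusion_t", 1:4)] <- 1e-6
  cfg$generating$theta_natural["meas_error"] <- 1e-6
  cfg$generating$theta_natural["practice_gain"] <- 0
  cfg$generating$re_sd[] <- 1e-12
  coh <- generate_cohort(cfg, seed = 3)
  cu3 <- unlist(lapply(coh[vapply(coh, `[[`, character(1), "group") == "CU"],
                       function(r) r$scores[3, ]))
  expect_true(all(abs(cu3 - cfg$generating$theta_natural["trial_3"]) < 1e-3))
})

test_that("integer scoring keeps every value in the word-list range", {
  cfg <- default_cohort_config()
  cfg$integer_scores <- TRUE
  coh <- generate_cohort(cfg, seed = 4)
  sc <- unlist(lapply(coh, `[[`, "scores"))
  expect_true(all(sc >= 0 & sc <= 12 & sc == round(sc)))
})

test_that("cohort CSV and config round-trips preserve content", {
  coh <- generate_cohort(small_cohort_config(), seed = 5)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  expect_length(back, length(coh))
  i <- 7L
  expect_equal(back[[i]]$scores, coh[[i]]$scores, tolerance = 1e-10)
  expect_equal(back[[i]]$group, coh[[i]]$group)
  expect_equal(back[[i]]$times, coh[[i]]$times, tolerance = 1e-10)

  yml <- tempfile(fileext = ".yaml")
  write_cohort_config(default_cohort_config(), yml)
  cfg <- read_cohort_config(yml)
  expect_equal(cfg$group_sizes, default_cohort_config()$group_sizes)
  expect_equal(cfg$generating$theta_natural,
               default_cohort_config()$generating$theta_natural)
  expect_equal(unname(cfg$generating$re_corr),
               unname(default_cohort_config()$generating$re_corr),
               tolerance = 1e-9)

  m <- cohort_manifest(coh)
  expect_equal(m$seed, 5L)
  expect_equal(m$n_subjects, length(coh))
  jf <- tempfile(fileext = ".json")
  cohort_manifest(coh, jf)
  expect_equal(jsonlite::read_json(jf)$config_hash, m$config_hash)
})

test_that("generated score moments match the model-implied moments", {
  # many subjects on one schedule: empirical mean/covariance of the scores
  # must match the analytic occasion-level moments including random effects
  gen <- default_cohort_config()$generating
  theta_u <- ctpe:::unconstrained_from_natural(gen$theta_natural)
  pop <- list(theta = theta_u, B = matrix(numeric(0), 12, 0),
              diffusion_corr = gen$diffusion_corr, variant = "standard",
              re_subset = names(gen$re_sd))
  spec0 <- subject_spec(pop)
  times <- c(0, 1.09, 2.18)
  D <- (gen$re_sd %o% gen$re_sd) * gen$re_corr
  n <- 10000L
  set.seed(17)
  U <- ctpe:::rmvnorm_chol(n, numeric(5), D)
  Y <- matrix(NA_real_, n, 12)
  for (i in seq_len(n)) {
    u <- U[i, ]
    names(u) <- names(gen$re_sd)
    sp <- subject_spec(pop, u = u)
    Y[i, ] <- as.vector(ctpe:::simulate_subjects_matrix(sp, times, 1L)[, , 1])
  }
  jm <- ctpe:::joint_obs_moments(spec0, times)
  g <- ctpe:::practice_unit_levels(spec0$drift_practice, times)
  A <- cbind(kronecker(rep(1, 3), diag(4)), kronecker(g, rep(1, 4)))
  S <- jm$cov + A %*% D %*% t(A)
  se_mean <- sqrt(diag(S) / n)
  expect_true(all(abs(colMeans(Y) - jm$mean) < 4 * se_mean))
  covbound <- 5 * sqrt((outer(diag(S), diag(S)) + S^2) / n)
  expect_true(all(abs(stats::cov(Y) - S) < covbound))
})
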