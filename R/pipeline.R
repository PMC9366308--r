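# End-to-end orchestration: the model suite (diagnosis-groups model, three
# sensitivity models, nine subgroup models, reparametrized variant),
# expectation curves, and tidy CSV outputs.

#' The full study plan of model configurations
#'
#' Fourteen independent fits: the diagnosis-groups model; three sensitivity
#' models adding age, sex or education with diagnosis interactions; nine
#' subgroup models (each diagnosis group crossed with each covariate); and
#' the reparametrized diagnosis-groups model estimating baseline performance
#' plus trial 2-4 deviations.
#'
#' @param optim optimizer settings passed to every [model_config()].
#' @return named list of `pe_model_config` objects.
#' @export
study_plan <- function(optim = list(maxit = 400L, factr = 1e8)) {
  plan <- list(diagnostic = model_config("none", "all", "standard",
                                         optim = optim))
  for (cv in c("age", "sex", "education")) {
    plan[[paste0("sens_", cv)]] <-
      model_config(cv, "all", "standard", optim = optim)
  }
  for (g in c("CU", "MCI", "DAT")) {
    for (cv in c("age", "sex", "education")) {
      plan[[paste0(tolower(g), "_", cv)]] <-
        model_config(cv, g, "standard", optim = optim)
    }
  }
  plan$reparam <- model_config("none", "all", "reparametrized", optim = optim)
  plan
}

#' Fit every model in a study plan
#'
#' Fits each configuration independently, summarizes it, and (optionally)
#' writes one summary CSV per model with columns `model`, `parameter`,
#' `mean`, `sd`, `ci2.5`, `ci97.5`, `flag`. A model whose subgroup filter
#' leaves fewer than two subjects, or whose fit fails, is skipped with a
#' logged reason; the rest of the bundle completes.
#'
#' @param plan named list of [model_config()]s (see [study_plan()]).
#' @param records list of subject records.
#' @param seed integer seed (initialization jitter and summary draws).
#' @param out_dir optional directory for per-model summary CSVs.
#' @param n_draws draws for [summarize_fit()].
#' @return list with `fits`, `summaries` and a `log` data frame (model,
#'   status, iterations, objective, gradient norm, seconds, reason).
#' @export
run_plan <- function(plan, records, seed = 1, out_dir = NULL,
                     n_draws = 2000L) {
  stopifnot(length(plan) > 0L, !is.null(names(plan)),
            !anyDuplicated(names(plan)))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  fits <- list()
  summaries <- list()
  log_rows <- list()
  for (nm in names(plan)) {
    cfg <- plan[[nm]]
    res <- tryCatch({
      fit <- fit_map(records, cfg, seed = seed)
      smry <- summarize_fit(fit, n_draws = n_draws, seed = seed)
      list(fit = fit, smry = smry, reason = "")
    }, error = function(e) list(fit = NULL, smry = NULL,
                                reason = conditionMessage(e)))
    if (is.null(res$fit)) {
      log_rows[[nm]] <- data.frame(
        model = nm, status = "skipped", iterations = NA_integer_,
        objective = NA_real_, gradient_norm = NA_real_,
        seconds = NA_real_, reason = res$reason, stringsAsFactors = FALSE
      )
      next
    }
    fits[[nm]] <- res$fit
    out <- cbind(model = nm, res$smry, stringsAsFactors = FALSE)
    summaries[[nm]] <- out
    cv <- res$fit$convergence
    log_rows[[nm]] <- data.frame(
      model = nm, status = if (cv$converged) "converged" else "not_converged",
      iterations = cv$iterations, objective = res$fit$value,
      gradient_norm = cv$gradient_norm, seconds = cv$seconds,
      reason = "", stringsAsFactors = FALSE
    )
    if (!is.null(out_dir)) {
      utils::write.csv(out, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  list(fits = fits, summaries = summaries,
       log = do.call(rbind, c(log_rows, make.row.names = FALSE)))
}

#' Covariate scenarios for expectation curves
#'
#' The baseline scenario sets every design column to zero; each additional
#' scenario sets one design column to +1 or -1 with all others zero. For
#' interaction columns this shows only the interaction effect, not the
#' interaction plus main effects.
#'
#' @param config a [model_config()].
#' @return named list of design vectors.
#' @export
expectation_scenarios <- function(config) {
  cols <- design_cols(config)
  out <- list(baseline = stats::setNames(numeric(length(cols)), cols))
  for (cc in cols) {
    for (s in c(1, -1)) {
      v <- out$baseline
      v[cc] <- s
      out[[sprintf("%s%+d", cc, s)]] <- v
    }
  }
  out
}

#' Model-implied expectation curves per covariate scenario
#'
#' Resolves the fitted population specification under each scenario (random
#' effects at zero) and evaluates the expected score for every trial over a
#' time grid, with the practice increment appearing as a jump immediately
#' after each occasion.
#'
#' @param fit a converged [fit_map()] result.
#' @param scenarios named list of design vectors (default:
#'   [expectation_scenarios()] of the fitted model).
#' @param occasions occasion times defining when practice increments occur
#'   (default: four occasions at the emulated mean interval of 1.09 years).
#' @param grid evaluation grid (default: 0.01-year resolution over the
#'   occasion span).
#' @return tidy `data.frame` with columns `scenario`, `trial`, `time`,
#'   `expected_score`.
#' @export
expectation_curves <- function(fit, scenarios = NULL,
                               occasions = c(0, 1.09, 2.18, 3.27),
                               grid = NULL) {
  stopifnot(inherits(fit, "pe_fit"))
  if (!fit$convergence$converged) {
    warning("computing expectation curves from a non-converged fit",
            call. = FALSE)
  }
  cols <- design_cols(fit$config)
  if (is.null(scenarios)) scenarios <- expectation_scenarios(fit$config)
  if (is.null(grid)) grid <- seq(0, max(occasions), by = 0.01)
  pop <- list(theta = fit$theta_hat, B = fit$B_hat,
              diffusion_corr = fit$diffusion_corr,
              variant = fit$config$variant,
              re_subset = fit$config$re_subset)
  out <- do.call(rbind, lapply(names(scenarios), function(nm) {
    d <- scenarios[[nm]]
    if (length(d) != length(cols) ||
        (length(d) > 0L && !setequal(names(d), cols))) {
      stop("scenario '", nm, "' does not match the fitted design columns (",
           paste(cols, collapse = ", "), ")")
    }
    spec <- subject_spec(pop, design_row = d[cols])
    cbind(scenario = nm, trajectory_expectation(spec, occasions, grid),
          stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[, c("scenario", "trial", "time", "expected_score")]
}

#' Read and write model configurations as YAML
#'
#' @param config a [model_config()].
#' @param path file path.
#' @return `read_model_config()` returns a `pe_model_config`.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "pe_model_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  obj <- yaml::read_yaml(path)
  model_config(
    covariate = obj$covariate %||% "none",
    subgroup = obj$subgroup %||% "all",
    variant = obj$variant %||% "standard",
    re_subset = obj$re_subset,
    priors = utils::modifyList(default_priors(), obj$priors %||% list()),
    optim = utils::modifyList(list(maxit = 400L, factr = 1e8),
                              obj$optim %||% list()),
    seed_jitter_sd = obj$seed_jitter_sd %||% 0.01
  )
}
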