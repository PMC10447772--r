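#' Fit a Gamma-Poisson panel model end to end
#'
#' Convenience wrapper: builds the design from a panel, samples the
#' posterior, computes convergence diagnostics, and summarizes every slope
#' with the posterior mean, posterior SD, and 89% HPDI.
#'
#' @param panel A `panel_table`.
#' @param model_kind `"mundlak"`, `"fixed_effects"`, or `"random_intercept"`.
#' @param adjusted Include crime-rate covariates and their interaction.
#' @param sampler A [sampler_config()].
#' @param model Optional [model_config()] overriding the default priors.
#' @param mass HPDI mass for the summary table.
#' @return A `gp_fit` list: `data`, `posterior`, `diagnostics`, `summary`.
#' @export
fit_model <- function(panel, model_kind = "mundlak", adjusted = TRUE,
                      sampler = sampler_config(), model = NULL, mass = 0.89) {
  data <- build_model_data(panel, model_kind, adjusted)
  posterior <- sample_posterior(data, model = model, sampler = sampler)
  diagnostics <- diagnose(posterior)
  structure(
    list(
      data = data,
      posterior = posterior,
      diagnostics = diagnostics,
      summary = posterior_summary(posterior, mass = mass)
    ),
    class = "gp_fit"
  )
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("<gp_fit> ", x$data$model_kind,
      if (x$data$adjusted) " (adjusted)" else " (unadjusted)", "\n", sep = "")
  print(x$summary)
  bad <- x$diagnostics$rhat[!is.na(x$diagnostics$rhat)] > 1.05
  if (any(bad)) {
    cat("WARNING: ", sum(bad), " parameter(s) with split R-hat > 1.05\n",
        sep = "")
  }
  invisible(x)
}

#' Parameter-recovery study over replicate synthetic panels
#'
#' Repeatedly simulates panels from a generator configuration, fits the
#' requested model variants to each, and records how well the gun-ownership
#' slope is recovered: posterior mean, posterior SD, the 89% HPDI and
#' whether it covers the generating truth, and the bias. Replicate seeds are
#' derived deterministically from the generator seed.
#'
#' @param config A [generator_config()]; its `seed` seeds replicate 1.
#' @param n_reps Number of replicate panels.
#' @param models Character vector of model variants to fit per replicate.
#' @param adjusted Fit with crime-rate covariates (default TRUE, matching
#'   the generator's nonzero crime slopes).
#' @param sampler A [sampler_config()] shared by every fit (its seed is
#'   offset per replicate).
#' @param mass HPDI mass used for the coverage flag.
#' @return Tibble with one row per replicate x model: `rep`, `model`,
#'   `true`, `estimate`, `se`, `lower`, `upper`, `covered`, `bias`,
#'   `rhat`, `ess`.
#' @export
recovery_study <- function(config = generator_config(), n_reps = 20,
                           models = c("mundlak", "fixed_effects"),
                           adjusted = TRUE,
                           sampler = sampler_config(n_chains = 2,
                                                    n_warmup = 500,
                                                    n_samples = 500),
                           mass = 0.89) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  rows <- list()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- (config$seed + 104729L * (r - 1L)) %% .Machine$integer.max
    sim <- simulate_panel(cfg)
    true_b <- sim$truth$beta[["gun"]]
    for (mk in models) {
      scfg <- sampler
      scfg$seed <- (sampler$seed + 7919L * r + match(mk, models)) %%
        .Machine$integer.max
      fit <- fit_model(sim$panel, model_kind = mk, adjusted = adjusted,
                       sampler = scfg, mass = mass)
      s <- summarize_posterior(fit$posterior, "b_gun", mass)
      dg <- fit$diagnostics
      rows[[length(rows) + 1]] <- tibble::tibble(
        rep = r, model = mk, true = true_b,
        estimate = s$mean, se = s$se,
        lower = s$interval$lower, upper = s$interval$upper,
        covered = true_b >= s$interval$lower & true_b <= s$interval$upper,
        bias = s$mean - true_b,
        rhat = dg$rhat[dg$parameter == "b_gun"],
        ess = dg$ess[dg$parameter == "b_gun"]
      )
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a recovery study into coverage and bias per model
#'
#' @param results Tibble from [recovery_study()].
#' @return Tibble per model: `n_reps`, `coverage` (fraction of replicates
#'   whose HPDI covered the truth), `mean_bias`, `bias_mc_se` (Monte-Carlo
#'   standard error of the mean bias), and `mean_se` (average posterior SD).
#' @export
recovery_summary <- function(results) {
  do.call(rbind, lapply(split(results, results$model), function(d) {
    tibble::tibble(
      model = d$model[1],
      n_reps = nrow(d),
      coverage = mean(d$covered),
      mean_bias = mean(d$bias),
      bias_mc_se = stats::sd(d$bias) / sqrt(nrow(d)),
      mean_se = mean(d$se)
    )
  }))
}

#' Write posterior draws to a columnar CSV
#'
#' One row per (chain, iteration) with one column per parameter.
#'
#' @param posterior A `posterior_draws` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_draws <- function(posterior, path) {
  d <- dim(posterior$draws)
  flat <- matrix(aperm(posterior$draws, c(2, 1, 3)), nrow = d[1] * d[2],
                 dimnames = list(NULL, posterior$parameter_names))
  out <- data.frame(
    chain = rep(seq_len(d[1]), each = d[2]),
    iteration = rep(seq_len(d[2]), times = d[1]),
    flat, check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest for an artifact directory
#'
#' Records what produced the artifacts: the command label, the seed, a hash
#' of the input file (when given), the package version, and a timestamp.
#'
#' @param path Output path of the manifest JSON.
#' @param command Short label of the pipeline step.
#' @param seed Integer seed used by the step.
#' @param config Optional configuration list, stored verbatim.
#' @param data_file Optional input file to fingerprint with MD5.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, command, seed, config = NULL,
                           data_file = NULL) {
  manifest <- list(
    command = command,
    seed = seed,
    config = config,
    data_hash = if (!is.null(data_file)) unname(tools::md5sum(data_file)),
    package_version = as.character(utils::packageVersion("gppanel")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
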