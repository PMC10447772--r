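test_that("identical seeds give bit-identical draws", {
  sim <- simulate_panel(generator_config(n_states = 6, n_years = 4, seed = 2))
  md <- build_model_data(sim$panel, "mundlak", adjusted = FALSE)
  cfg <- sampler_config(n_chains = 2, n_warmup = 100, n_samples = 100, seed = 9)
  a <- sample_posterior(md, sampler = cfg)
  b <- sample_posterior(md, sampler = cfg)
  expect_identical(a$draws, b$draws)
  c <- sample_posterior(md, sampler = sampler_config(2, 100, 100, seed = 10))
  expect_false(identical(a$draws, c$draws))
})

test_that("the Poisson-limit intercept posterior matches the conjugate form", {
  # One state, no covariate signal, huge fixed dispersion, flat-ish prior:
  # with a flat prior on alpha, exp(alpha) | y ~ Gamma(sum(y), n), so
  # E[alpha | y] = digamma(sum(y)) - log(n).
  set.seed(31)
  n <- 40
  y <- stats::rpois(n, 5)
  md <- toy_model_data(y = y, log_offset = rep(0, n),
                       group_index = rep(1, n), G_std = rep(0, n))
  model <- model_config("fixed_effects", adjusted = FALSE,
                        alpha_bar_mean = 0, alpha_bar_sd = 10,
                        fixed_phi = 1e8)
  post <- sample_posterior(md, model = model,
                           sampler = sampler_config(2, 1000, 2000, seed = 5))
  draws <- parameter_draws(post, "alpha[1]")
  analytic <- digamma(sum(y)) - log(n)
  mcse <- stats::sd(draws) / sqrt(effective_sample_size(draws))
  expect_lt(abs(mean(draws) - analytic), 3 * mcse + 1e-4)
  # conjugate posterior SD: sqrt(trigamma(sum y))
  expect_equal(stats::sd(draws), sqrt(trigamma(sum(y))), tolerance = 0.1)
})

test_that("chains converge on a synthetic Mundlak panel", {
  sim <- simulate_panel(generator_config(n_states = 15, n_years = 8, seed = 4))
  fit <- fit_model(sim$panel, "mundlak", adjusted = TRUE,
                   sampler = sampler_config(2, 500, 500, seed = 6))
  dg <- fit$diagnostics
  expect_true(all(dg$rhat < 1.1, na.rm = TRUE))
  expect_gt(dg$ess[dg$parameter == "b_gun"], 100)
  # all draws finite, constrained parameters positive on the natural scale
  expect_true(all(is.finite(fit$posterior$draws)))
  expect_true(all(parameter_draws(fit$posterior, "tau") > 0))
  expect_true(all(parameter_draws(fit$posterior, "phi") > 0))
})

test_that("impossible data trigger an initialization failure", {
  md <- toy_model_data(y = 1, log_offset = 1000, group_index = 1, G_std = 0)
  expect_error(
    suppressWarnings(
      sample_posterior(md, model = model_config("fixed_effects", FALSE),
                       sampler = sampler_config(2, 10, 10, seed = 1))
    ),
    "initialization failure"
  )
})

test_that("built-in and external (JAGS) backends agree on a small panel", {
  skip_if_not_installed("rjags")
  sim <- simulate_panel(generator_config(n_states = 10, n_years = 6, seed = 8))
  md <- build_model_data(sim$panel, "mundlak", adjusted = FALSE)
  a <- sample_posterior(md, sampler = sampler_config(2, 600, 800, seed = 3))
  b <- sample_posterior(md, sampler = sampler_config(2, 600, 800, seed = 3,
                                                     backend = "external"))
  for (p in c("b_gun", "phi")) {
    da <- parameter_draws(a, p); db <- parameter_draws(b, p)
    mcse <- sqrt(stats::sd(da)^2 / effective_sample_size(da) +
                   stats::sd(db)^2 / effective_sample_size(db))
    expect_lt(abs(mean(da) - mean(db)), 4 * mcse)
  }
})

test_that("model/data configuration mismatches are rejected", {
  sim <- simulate_panel(generator_config(n_states = 4, n_years = 3, seed = 1))
  md <- build_model_data(sim$panel, "mundlak", adjusted = FALSE)
  expect_error(
    sample_posterior(md, model = model_config("fixed_effects", FALSE),
                     sampler = sampler_config(2, 10, 10)),
    "configuration error"
  )
  expect_error(sampler_config(n_chains = 1), "n_chains")
})
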