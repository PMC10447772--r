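test_that("gamma_poisson_log_pmf matches special cases and the mixture oracle", {
  # phi = 1 geometric: P(0) = phi / (phi + lam) = 1/2
  expect_equal(gamma_poisson_log_pmf(0, 1, 1), log(0.5))
  # phi -> Inf Poisson limit
  expect_equal(gamma_poisson_log_pmf(3, 2, 1e8),
               stats::dpois(3, 2, log = TRUE), tolerance = 1e-6)
  # quadrature over the Poisson-Gamma mixture
  mix <- stats::integrate(
    function(mu) stats::dpois(5, mu) * stats::dgamma(mu, shape = 2, rate = 2 / 4),
    0, Inf, rel.tol = 1e-12
  )$value
  expect_equal(gamma_poisson_log_pmf(5, 4, 2), log(mix), tolerance = 1e-8)

  expect_error(gamma_poisson_log_pmf(-1, 1, 1), "non-negative integer")
  expect_error(gamma_poisson_log_pmf(1.5, 1, 1), "non-negative integer")
  expect_error(gamma_poisson_log_pmf(1, 0, 1), "lam")
  expect_error(gamma_poisson_log_pmf(1, 1, -2), "phi")
  # no overflow at large counts
  expect_true(is.finite(gamma_poisson_log_pmf(1e6, 1e6, 5)))
})

test_that("the pmf is properly normalized and has the stated moments", {
  for (lam in c(0.5, 5, 50)) {
    for (phi in c(0.5, 2, 20)) {
      y_max <- stats::qnbinom(1e-12, size = phi, mu = lam, lower.tail = FALSE)
      total <- sum(exp(gamma_poisson_log_pmf(0:y_max, lam, phi)))
      expect_gte(total, 1 - 1e-6)
      expect_lte(total, 1 + 1e-12)
    }
  }
  # Monte-Carlo draws from the mixture match mean lam, variance lam + lam^2/phi
  set.seed(99)
  lam <- 6; phi <- 2
  y <- stats::rpois(2e5, stats::rgamma(2e5, shape = phi, rate = phi / lam))
  expect_equal(mean(y), lam, tolerance = 0.02)
  expect_equal(stats::var(y), lam + lam^2 / phi, tolerance = 0.05)
})

test_that("linear_predictor sums the active terms", {
  # offset-only when everything is zero
  md <- toy_model_data(y = c(1, 2, 3), log_offset = c(5, 6, 7),
                       group_index = c(1, 1, 2), G_std = c(0.1, -0.2, 0.4))
  p0 <- list(alpha = c(0, 0), beta = 0, phi = 1)
  expect_equal(linear_predictor(md, p0), md$log_offset)

  # single-observation arithmetic identity: 10 - 10 + 0.5 * 2 = 1
  md1 <- toy_model_data(y = 3, log_offset = 10, group_index = 1, G_std = 2)
  expect_equal(linear_predictor(md1, list(alpha = -10, beta = 0.5, phi = 1)), 1)

  # four observations vs a hand loop over every term, Mundlak adjusted
  md4 <- toy_model_data(
    y = c(1, 2, 3, 4), log_offset = c(10, 10.5, 11, 11.5),
    group_index = c(1, 1, 2, 2), G_std = c(-1, -0.5, 0.5, 1),
    VC_std = c(0.2, -0.2, 0.1, -0.1), PC_std = c(1, -1, 0.5, -0.5),
    G_bar_by_state = c(-0.75, 0.75),
    model_kind = "mundlak", adjusted = TRUE
  )
  params <- list(alpha_bar = -10, tau = 1, alpha = c(-10.2, -9.8),
                 beta = c(0.06, 0.1, 0.05, -0.02, 0.3), phi = 5)
  oracle <- vapply(1:4, function(i) {
    g <- md4$group_index[i]
    md4$log_offset[i] + params$alpha[g] + 0.06 * md4$G_std[i] +
      0.1 * md4$VC_std[i] + 0.05 * md4$PC_std[i] +
      -0.02 * md4$VC_std[i] * md4$PC_std[i] + 0.3 * md4$G_bar_by_state[g]
  }, numeric(1))
  expect_equal(linear_predictor(md4, params), oracle, tolerance = 1e-12)

  # FE and Mundlak agree when the group-mean slope is zero
  md4_fe <- md4
  md4_fe$model_kind <- "fixed_effects"
  md4_fe$G_bar_by_state <- NULL
  params5 <- params
  params5$beta[5] <- 0
  params_fe <- list(alpha = params$alpha, beta = params$beta[1:4], phi = 5)
  expect_equal(linear_predictor(md4, params5),
               linear_predictor(md4_fe, params_fe))

  expect_error(linear_predictor(md4, list(alpha = -10, beta = 1:2, phi = 1)),
               "configuration error")
})

test_that("log_likelihood reduces to the pmf and adds over observations", {
  md1 <- toy_model_data(y = 5, log_offset = 0, group_index = 1, G_std = 0)
  p1 <- list(alpha = log(4), beta = 0, phi = 2)
  expect_equal(log_likelihood(md1, p1), gamma_poisson_log_pmf(5, 4, 2))

  md2 <- toy_model_data(y = c(5, 2), log_offset = c(0, 0),
                        group_index = c(1, 1), G_std = c(0, 1))
  p2 <- list(alpha = log(4), beta = 0.3, phi = 2)
  expect_equal(log_likelihood(md2, p2),
               gamma_poisson_log_pmf(5, 4, 2) +
                 gamma_poisson_log_pmf(2, 4 * exp(0.3), 2))

  set.seed(7)
  md10 <- toy_model_data(y = rpois(10, 20), log_offset = runif(10, 9, 11),
                         group_index = rep(1:2, each = 5),
                         G_std = rnorm(10))
  p10 <- list(alpha = c(-7.5, -7.2), beta = 0.1, phi = 4)
  eta <- linear_predictor(md10, p10)
  oracle <- sum(vapply(seq_len(10), function(i) {
    gamma_poisson_log_pmf(md10$y[i], exp(eta[i]), 4)
  }, numeric(1)))
  expect_equal(log_likelihood(md10, p10), oracle, tolerance = 1e-12)

  # overflowing predictor is flagged and rejected, not propagated as NaN
  md_over <- toy_model_data(y = 1, log_offset = 1000, group_index = 1, G_std = 0)
  expect_warning(ll <- log_likelihood(md_over, p1), "overflow")
  expect_identical(ll, -Inf)
})

test_that("log_prior matches closed forms and support boundaries", {
  cfg <- model_config("mundlak", adjusted = TRUE)
  S <- 3
  params <- list(alpha_bar = -10, tau = 1, alpha = rep(-10, S),
                 beta = rep(0, 5), phi = 1)
  oracle <- stats::dnorm(-10, -10, 1, log = TRUE) +
    stats::dexp(1, 1, log = TRUE) +
    S * stats::dnorm(-10, -10, 1, log = TRUE) +
    5 * stats::dnorm(0, 0, 1, log = TRUE) +
    stats::dexp(1, 1, log = TRUE)
  expect_equal(log_prior(params, cfg), oracle, tolerance = 1e-12)

  bad <- params; bad$tau <- -0.5
  expect_identical(log_prior(bad, cfg), -Inf)
  bad2 <- params; bad2$phi <- 0
  expect_identical(log_prior(bad2, cfg), -Inf)

  # each additional slope at zero contributes exactly one standard-normal
  # log density
  more <- params; more$beta <- rep(0, 6)
  expect_equal(log_prior(more, cfg) - log_prior(params, cfg),
               stats::dnorm(0, log = TRUE))

  # FE prior: independent Normal(-10, 1) per state, no hyperparameters
  fe_cfg <- model_config("fixed_effects", adjusted = FALSE)
  fe_params <- list(alpha = c(-9, -11), beta = 0.5, phi = 2)
  fe_oracle <- sum(stats::dnorm(c(-9, -11), -10, 1, log = TRUE)) +
    stats::dnorm(0.5, 0, 1, log = TRUE) + stats::dexp(2, 1, log = TRUE)
  expect_equal(log_prior(fe_params, fe_cfg), fe_oracle, tolerance = 1e-12)
})

test_that("log_posterior is the exact sum and is order invariant", {
  md <- toy_model_data(y = c(4, 9, 2), log_offset = c(8, 8.5, 9),
                       group_index = c(1, 2, 2), G_std = c(-1, 0, 1))
  cfg <- model_config("fixed_effects", adjusted = FALSE)
  params <- list(alpha = c(-6.5, -7), beta = 0.2, phi = 3)
  expect_equal(log_posterior(md, params, cfg),
               log_likelihood(md, params) + log_prior(params, cfg))

  perm <- c(3, 1, 2)
  md_p <- toy_model_data(y = md$y[perm], log_offset = md$log_offset[perm],
                         group_index = md$group_index[perm],
                         G_std = md$G_std[perm])
  expect_equal(log_posterior(md_p, params, cfg),
               log_posterior(md, params, cfg), tolerance = 1e-12)

  bad <- params; bad$phi <- -1
  expect_identical(log_posterior(md, bad, cfg), -Inf)
})
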