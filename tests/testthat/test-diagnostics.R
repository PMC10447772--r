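test_that("split_rhat is near 1 for matching chains and large for split ones", {
  set.seed(11)
  good <- rbind(rnorm(5000), rnorm(5000))
  expect_gte(split_rhat(good), 1 - 1e-6)
  expect_lte(split_rhat(good), 1.02)

  # two chains stuck at different values: direct W/B evaluation
  set.seed(12)
  a <- rnorm(100, 0, 0.01)
  b <- rnorm(100, 10, 0.01)
  stuck <- rbind(a, b)
  expect_gt(split_rhat(stuck), 1.5)
  half <- 50
  halves <- rbind(a[1:50], a[51:100], b[1:50], b[51:100])
  W <- mean(apply(halves, 1, var))
  B <- half * var(rowMeans(halves))
  expect_equal(split_rhat(stuck),
               sqrt(((half - 1) / half * W + B / half) / W),
               tolerance = 1e-12)

  expect_identical(split_rhat(matrix(1, 2, 100)), NA_real_)
  expect_error(split_rhat(matrix(1:4, 1)), "chains")
})

test_that("split_rhat approaches 1 as same-target chains lengthen", {
  set.seed(13)
  draws <- matrix(rnorm(4 * 1e4), nrow = 4)
  expect_lt(split_rhat(draws), 1.01)
  expect_lt(split_rhat(draws, rank_normalize = TRUE), 1.01)
})

test_that("effective_sample_size matches independence and AR(1) oracles", {
  set.seed(14)
  iid <- matrix(rnorm(4 * 500), nrow = 4)
  ess <- effective_sample_size(iid)
  expect_gte(ess, 1600)
  expect_lte(ess, 2400)

  # AR(1) with rho = 0.9: asymptotic ESS = total * (1 - rho) / (1 + rho)
  rho <- 0.9
  ar <- t(replicate(4, as.vector(
    stats::arima.sim(list(ar = rho), 4000, sd = sqrt(1 - rho^2))
  )))
  ess_ar <- effective_sample_size(ar)
  expect_gt(ess_ar, 16000 / 19 / 2)
  expect_lt(ess_ar, 16000 / 19 * 2)

  expect_identical(effective_sample_size(matrix(3, 2, 100)), NA_real_)
})

test_that("hpdi equals the exhaustive shortest-window search", {
  iv <- hpdi(1:100, 0.89)
  # brute force over the 12 candidate windows of 89 consecutive values
  oracle <- hpdi_brute(1:100, 0.89)
  expect_equal(c(iv$lower, iv$upper), oracle)
  expect_equal(iv$upper - iv$lower, 88)

  same <- hpdi(rep(2.5, 50))
  expect_equal(same$lower, 2.5)
  expect_equal(same$upper, 2.5)

  set.seed(15)
  for (rep in 1:25) {
    n <- sample(10:500, 1)
    mass <- runif(1, 0.5, 0.99)
    x <- switch(sample(3, 1),
                rnorm(n), rexp(n), sample(0:20, n, replace = TRUE))
    got <- hpdi(x, mass)
    expect_equal(c(got$lower, got$upper), hpdi_brute(x, mass))
    # never wider than the equal-tailed (central) interval on the same draws
    s <- sort(x)
    m <- ceiling(mass * n)
    lo <- floor((n - m) / 2) + 1
    expect_lte(got$upper - got$lower, s[lo + m - 1] - s[lo] + 1e-12)
  }

  # symmetric unimodal draws give a near-symmetric interval
  set.seed(16)
  x <- rnorm(1e4)
  iv <- hpdi(x)
  expect_lt(abs((iv$lower + iv$upper) / 2 - mean(x)), 0.05 * sd(x))

  expect_error(hpdi(1:5), "insufficient")
  expect_error(hpdi(1:50, mass = 1.2), "mass")
})

test_that("summarize_posterior reports the mean/SD/HPDI triple", {
  flat <- fake_posterior(list(b_gun = 0.5))
  s <- summarize_posterior(flat, "b_gun")
  expect_equal(s$mean, 0.5)
  expect_equal(s$se, 0)
  expect_equal(s$interval$lower, 0.5)
  expect_equal(s$interval$upper, 0.5)

  set.seed(17)
  x <- rnorm(4000)
  post <- fake_posterior(list(b_gun = x), n_chains = 2, n_iter = 2000)
  s2 <- summarize_posterior(post, "b_gun")
  expect_equal(s2$mean, mean(x))
  expect_equal(s2$se, sd(x))
  expect_equal(c(s2$interval$lower, s2$interval$upper), hpdi_brute(x, 0.89))

  expect_error(summarize_posterior(flat, "nope"), "unknown parameter")
})

test_that("diagnose covers every parameter and flags warnings", {
  sim <- simulate_panel(generator_config(n_states = 5, n_years = 4, seed = 21))
  md <- build_model_data(sim$panel, "fixed_effects", adjusted = FALSE)
  post <- sample_posterior(md, sampler = sampler_config(2, 100, 100, seed = 2))
  dg <- diagnose(post)
  expect_setequal(dg$parameter, setdiff(post$parameter_names, "lp__"))
  expect_true(all(dg$rhat >= 1 - 1e-6, na.rm = TRUE))
  expect_true(is.numeric(attr(dg, "sampler_warnings")))
})
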