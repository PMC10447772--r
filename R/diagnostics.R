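#' Split R-hat convergence diagnostic
#'
#' Each chain is split in half and the potential scale reduction factor
#' `sqrt(((N-1)/N * W + B/N) / W)` is computed over the resulting half
#' chains, where `W` is the mean within-half-chain variance and `B` the
#' between-half-chain variance of half-chain means scaled by the half
#' length. Values near 1 indicate that the chains agree; the conventional
#' alarm threshold is 1.01-1.05. When the draws carry no variance the
#' diagnostic is undefined and `NA` is returned (reported, never silently 1).
#'
#' @param draws Numeric matrix, chains in rows, iterations in columns.
#'   At least 2 chains and 4 iterations.
#' @param rank_normalize Apply the rank-normalization (inverse-normal
#'   transform of pooled average ranks) before computing the statistic.
#' @return Scalar R-hat, or `NA_real_` when undefined.
#' @export
split_rhat <- function(draws, rank_normalize = FALSE) {
  draws <- as.matrix(draws)
  m <- nrow(draws)
  n <- ncol(draws)
  if (m < 2 || n < 4) {
    stop("split_rhat needs >= 2 chains and >= 4 iterations", call. = FALSE)
  }
  if (rank_normalize) {
    r <- rank(as.vector(t(draws)), ties.method = "average")
    z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
    draws <- matrix(z, nrow = m, byrow = TRUE)
  }
  half <- floor(n / 2)
  halves <- rbind(draws[, seq_len(half), drop = FALSE],
                  draws[, seq.int(n - half + 1, n), drop = FALSE])
  w_vars <- apply(halves, 1, stats::var)
  W <- mean(w_vars)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- half * stats::var(rowMeans(halves))
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based effective sample size across chains: lagged
#' correlations are estimated from per-chain autocovariances combined with
#' the between-chain variance, summed in Geyer pairs with the initial
#' positive-sequence and monotone truncation. Independent draws give an ESS
#' close to the total draw count.
#'
#' @param draws Numeric matrix, chains in rows, iterations in columns.
#' @return Scalar ESS, or `NA_real_` for degenerate (constant) draws.
#' @export
effective_sample_size <- function(draws) {
  draws <- as.matrix(draws)
  m <- nrow(draws)
  n <- ncol(draws)
  if (m < 2 || n < 4) {
    stop("effective_sample_size needs >= 2 chains and >= 4 iterations",
         call. = FALSE)
  }
  chain_vars <- apply(draws, 1, stats::var)
  W <- mean(chain_vars)
  B_over_n <- stats::var(rowMeans(draws))
  var_plus <- (n - 1) / n * W + B_over_n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)

  # mean across chains of the biased (1/n) autocovariance at each lag
  max_lag <- n - 1
  acov <- matrix(0, nrow = m, ncol = max_lag + 1)
  for (ch in seq_len(m)) {
    acov[ch, ] <- stats::acf(draws[ch, ], lag.max = max_lag,
                             type = "covariance", demean = TRUE,
                             plot = FALSE)$acf[, 1, 1]
  }
  s_t <- colMeans(acov)
  rho <- 1 - (W - s_t) / var_plus # rho[1] is lag 0

  # Geyer initial positive + monotone sequence over paired sums
  n_pairs <- floor((max_lag + 1) / 2)
  tau <- 0
  prev <- Inf
  for (k in seq_len(n_pairs)) {
    p <- rho[2 * k - 1] + rho[2 * k]
    if (!is.finite(p) || p <= 0) break
    p <- min(p, prev)
    tau <- tau + p
    prev <- p
  }
  tau <- max(2 * tau - 1, 1 / (m * n)) # tau >= small positive guard
  (m * n) / tau
}

#' Convergence diagnostics for every parameter
#'
#' @param posterior A `posterior_draws` object.
#' @param rank_normalize Use rank-normalized split R-hat.
#' @return A tibble with `parameter`, `rhat`, and `ess`; the posterior's
#'   `sampler_warnings` count is attached as an attribute and printed by the
#'   report writers.
#' @export
diagnose <- function(posterior, rank_normalize = FALSE) {
  params <- setdiff(posterior$parameter_names, "lp__")
  res <- tibble::tibble(
    parameter = params,
    rhat = vapply(params, function(p) {
      split_rhat(parameter_draws(posterior, p), rank_normalize)
    }, numeric(1)),
    ess = vapply(params, function(p) {
      effective_sample_size(parameter_draws(posterior, p))
    }, numeric(1))
  )
  attr(res, "sampler_warnings") <- posterior$sampler_warnings
  res
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing at least `mass` of the draws:
#' draws are sorted and all windows of `ceiling(mass * n)` consecutive draws
#' are scanned for the smallest width, ties broken by the lowest lower
#' bound.
#'
#' @param draws Numeric vector of at least 10 draws.
#' @param mass Probability mass in (0, 1); default 0.89.
#' @return List with `lower`, `upper`, and `mass`.
#' @export
hpdi <- function(draws, mass = 0.89) {
  draws <- as.vector(draws)
  if (length(draws) < 10) {
    stop("insufficient data: hpdi needs at least 10 draws", call. = FALSE)
  }
  if (!(mass > 0 && mass < 1)) {
    stop("mass must be in (0, 1)", call. = FALSE)
  }
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) {
    return(list(lower = s[1], upper = s[n], mass = mass))
  }
  lo <- s[seq_len(n - m + 1)]
  hi <- s[seq.int(m, n)]
  i <- which.min(hi - lo) # first minimum = lowest lower bound on ties
  list(lower = lo[i], upper = hi[i], mass = mass)
}

#' Posterior mean, posterior SD, and HPDI for one parameter
#'
#' The reporting triple used throughout: the posterior mean, the posterior
#' standard deviation (reported as "SE"), and the highest posterior density
#' interval at the given mass (default 89%). Draws are pooled across chains.
#'
#' @param posterior A `posterior_draws` object.
#' @param parameter Parameter name.
#' @param mass HPDI probability mass; default 0.89.
#' @return List with `mean`, `se`, and `interval` (see [hpdi()]).
#' @export
summarize_posterior <- function(posterior, parameter, mass = 0.89) {
  x <- as.vector(parameter_draws(posterior, parameter))
  list(
    mean = mean(x),
    se = stats::sd(x),
    interval = hpdi(x, mass)
  )
}

#' Summary table over a set of parameters
#'
#' @param posterior A `posterior_draws` object.
#' @param parameters Character vector of parameter names; default all slope
#'   parameters (names starting with `b_`).
#' @param mass HPDI probability mass.
#' @return Tibble with `parameter`, `mean`, `se`, `hpdi_lower`, `hpdi_upper`.
#' @export
posterior_summary <- function(posterior, parameters = NULL, mass = 0.89) {
  if (is.null(parameters)) {
    parameters <- grep("^b_", posterior$parameter_names, value = TRUE)
  }
  rows <- lapply(parameters, function(p) {
    s <- summarize_posterior(posterior, p, mass)
    tibble::tibble(parameter = p, mean = s$mean, se = s$se,
                   hpdi_lower = s$interval$lower,
                   hpdi_upper = s$interval$upper)
  })
  do.call(rbind, rows)
}
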