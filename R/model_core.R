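#' Gamma-Poisson (negative binomial) log probability mass
#'
#' Log of `P(Y = y)` for the Gamma-Poisson distribution parameterized by mean
#' `lam` and shape `phi`, i.e. a Poisson whose rate is Gamma-distributed with
#' shape `phi` and rate `phi / lam`. The variance is `lam + lam^2 / phi`;
#' `phi -> Inf` recovers the Poisson. Parameterizations of the negative
#' binomial differ across software; this mean/shape convention is used
#' throughout the package.
#'
#' @param y Non-negative integer count(s).
#' @param lam Positive mean(s).
#' @param phi Positive shape (dispersion; larger means less overdispersion).
#' @return Log pmf value(s); computed through log-gamma functions so counts
#'   up to at least 1e6 do not overflow.
#' @export
gamma_poisson_log_pmf <- function(y, lam, phi) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    stop("y must be a non-negative integer", call. = FALSE)
  }
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("lam must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    stop("phi must be positive and finite", call. = FALSE)
  }
  stats::dnbinom(y, size = phi, mu = lam, log = TRUE)
}

#' Model configuration: variant, covariates, and prior hyperparameters
#'
#' Collects everything that defines a model beyond the data: which intercept
#' structure is used, whether the crime-rate covariates enter, and the prior
#' hyperparameters. Defaults are the weakly informative priors of the
#' analysis: partially pooled intercepts `alpha_s ~ Normal(alpha_bar, tau)`
#' with `alpha_bar ~ Normal(-10, 1)` and `tau ~ Exponential(1)` for the
#' Mundlak and random-intercept variants, independent `Normal(-10, 1)`
#' intercepts for the fixed-effects variant, `Normal(0, 1)` slopes, and
#' `Exponential(1)` on the dispersion `phi` (the dispersion prior is a
#' package convention; it can be overridden here, and `fixed_phi` pins the
#' dispersion entirely). Normal priors are (mean, sd).
#'
#' @param model_kind `"mundlak"`, `"fixed_effects"`, or `"random_intercept"`.
#' @param adjusted Include crime-rate covariates and their interaction.
#' @param alpha_bar_mean,alpha_bar_sd Prior on the grand intercept (pooled
#'   variants) or on each fixed intercept.
#' @param tau_rate Exponential rate for the intercept scale (pooled variants).
#' @param beta_sd Prior standard deviation of all slopes (mean 0).
#' @param phi_rate Exponential rate of the dispersion prior.
#' @param fixed_phi Optional positive value; when given, `phi` is held fixed
#'   and not sampled.
#' @return A `model_config` list.
#' @export
model_config <- function(model_kind = c("mundlak", "fixed_effects",
                                        "random_intercept"),
                         adjusted = TRUE,
                         alpha_bar_mean = -10, alpha_bar_sd = 1,
                         tau_rate = 1, beta_sd = 1, phi_rate = 1,
                         fixed_phi = NULL) {
  model_kind <- match.arg(model_kind)
  if (!is.null(fixed_phi) && (!is.finite(fixed_phi) || fixed_phi <= 0)) {
    stop("fixed_phi must be positive", call. = FALSE)
  }
  structure(
    list(
      model_kind = model_kind, adjusted = adjusted,
      alpha_bar_mean = alpha_bar_mean, alpha_bar_sd = alpha_bar_sd,
      tau_rate = tau_rate, beta_sd = beta_sd, phi_rate = phi_rate,
      fixed_phi = fixed_phi
    ),
    class = "model_config"
  )
}

# Slope names active for a given configuration, in design order.
beta_names <- function(model_kind, adjusted) {
  nm <- "b_gun"
  if (adjusted) nm <- c(nm, "b_vc", "b_pc", "b_vc_pc")
  if (model_kind == "mundlak") nm <- c(nm, "b_gun_bar")
  nm
}

# Validate a parameter list against a model_data configuration.
check_parameters <- function(data, params) {
  pooled <- data$model_kind %in% c("mundlak", "random_intercept")
  if (pooled) {
    if (is.null(params$alpha_bar) || is.null(params$tau)) {
      stop("configuration error: pooled intercepts need alpha_bar and tau",
           call. = FALSE)
    }
  }
  if (length(params$alpha) != data$n_states) {
    stop("configuration error: alpha must have one entry per state",
         call. = FALSE)
  }
  expected <- beta_names(data$model_kind, data$adjusted)
  if (length(params$beta) != length(expected)) {
    stop("configuration error: expected ", length(expected),
         " slope(s) (", paste(expected, collapse = ", "), "), got ",
         length(params$beta), call. = FALSE)
  }
  invisible(TRUE)
}

#' Linear predictor on the log-rate scale
#'
#' Elementwise sum of the log-population offset, the state intercept, the
#' standardized-exposure term, the crime-rate terms when the design is
#' adjusted, and the state-mean exposure term for the Mundlak variant.
#'
#' @param data A `model_data` object from [build_model_data()].
#' @param params List with `alpha` (length `n_states`), `beta` (in the order
#'   given by the design: gun, then vc/pc/vc_pc if adjusted, then gun_bar if
#'   Mundlak), and for pooled variants `alpha_bar` and `tau` (unused here but
#'   validated); `phi` is not needed.
#' @return Numeric vector of log expected counts, length `data$n`.
#' @export
linear_predictor <- function(data, params) {
  check_parameters(data, params)
  beta <- params$beta
  eta <- data$log_offset + params$alpha[data$group_index]
  k <- 1L
  eta <- eta + beta[k] * data$G_std
  if (data$adjusted) {
    eta <- eta + beta[k + 1L] * data$VC_std + beta[k + 2L] * data$PC_std +
      beta[k + 3L] * (data$VC_std * data$PC_std)
    k <- k + 3L
  }
  if (data$model_kind == "mundlak") {
    eta <- eta + beta[k + 1L] * data$G_bar_by_state[data$group_index]
  }
  eta
}

#' Gamma-Poisson log likelihood of a panel
#'
#' Sum over observations of the Gamma-Poisson log pmf at the rate implied by
#' [linear_predictor()] and dispersion `params$phi`. An overflowing linear
#' predictor yields `-Inf` with a warning, which samplers treat as a
#' rejected point.
#'
#' @inheritParams linear_predictor
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(data, params) {
  eta <- linear_predictor(data, params)
  lam <- exp(eta)
  if (any(!is.finite(lam))) {
    warning("overflow in exp(linear predictor); returning -Inf",
            call. = FALSE)
    return(-Inf)
  }
  sum(stats::dnbinom(data$y, size = params$phi, mu = lam, log = TRUE))
}

#' Log prior density of the model parameters
#'
#' Pooled variants (Mundlak, random intercept):
#' `Normal(alpha_bar | m, s) + Exponential(tau | rate) +
#'  sum_s Normal(alpha_s | alpha_bar, tau) + sum_k Normal(beta_k | 0, sd) +
#'  Exponential(phi | rate)`.
#' Fixed effects: independent `Normal(alpha_s | m, s)` per state plus the
#' slope and dispersion terms. Out-of-support `tau` or `phi` gives `-Inf`.
#'
#' @param params Parameter list (see [linear_predictor()]), plus `phi`.
#' @param config A [model_config()].
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, config) {
  pooled <- config$model_kind %in% c("mundlak", "random_intercept")
  lp <- 0
  if (pooled) {
    if (!is.finite(params$tau) || params$tau <= 0) return(-Inf)
    lp <- lp +
      stats::dnorm(params$alpha_bar, config$alpha_bar_mean,
                   config$alpha_bar_sd, log = TRUE) +
      stats::dexp(params$tau, config$tau_rate, log = TRUE) +
      sum(stats::dnorm(params$alpha, params$alpha_bar, params$tau, log = TRUE))
  } else {
    lp <- lp + sum(stats::dnorm(params$alpha, config$alpha_bar_mean,
                                config$alpha_bar_sd, log = TRUE))
  }
  lp <- lp + sum(stats::dnorm(params$beta, 0, config$beta_sd, log = TRUE))
  if (is.null(config$fixed_phi)) {
    if (!is.finite(params$phi) || params$phi <= 0) return(-Inf)
    lp <- lp + stats::dexp(params$phi, config$phi_rate, log = TRUE)
  }
  lp
}

#' Log posterior density (unnormalized)
#'
#' The sum of [log_likelihood()] and [log_prior()]; `-Inf` outside the
#' support. Invariant to the ordering of observations.
#'
#' @inheritParams log_likelihood
#' @param config A [model_config()] consistent with `data`.
#' @return Scalar unnormalized log posterior.
#' @export
log_posterior <- function(data, params, config) {
  lp <- log_prior(params, config)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(data, params)
}
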