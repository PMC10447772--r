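#' Sampler configuration
#'
#' Settings for the built-in adaptive random-walk Metropolis sampler. At
#' least two chains are required so that split R-hat is defined. Positive
#' parameters (the intercept scale `tau` and the dispersion `phi`) are
#' sampled on the log scale with the Jacobian adjustment; proposal scales are
#' tuned per block during warmup and frozen afterwards.
#'
#' @param n_chains Number of chains (>= 2).
#' @param n_warmup Warmup (adaptation) iterations per chain, discarded.
#' @param n_samples Post-warmup iterations kept per chain.
#' @param seed Integer seed; the full run is reproducible bit-for-bit under
#'   the built-in backend.
#' @param adapt_window Iterations between proposal-scale updates in warmup.
#' @param backend `"built_in"` (the adaptive Metropolis sampler implemented
#'   here) or `"external"` (Gibbs sampling through JAGS via the rjags
#'   package, used as an independent cross-check).
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_chains = 4, n_warmup = 1000, n_samples = 1000,
                           seed = 1, adapt_window = 50,
                           backend = c("built_in", "external")) {
  if (n_chains < 2) stop("n_chains must be >= 2", call. = FALSE)
  if (n_warmup < 0 || n_samples < 1) {
    stop("n_warmup must be >= 0 and n_samples >= 1", call. = FALSE)
  }
  structure(
    list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
         n_samples = as.integer(n_samples), seed = as.integer(seed),
         adapt_window = as.integer(adapt_window),
         backend = match.arg(backend)),
    class = "sampler_config"
  )
}

# Active design matrix for the slope terms, columns in beta_names() order.
design_matrix <- function(data) {
  cols <- list(b_gun = data$G_std)
  if (data$adjusted) {
    cols$b_vc <- data$VC_std
    cols$b_pc <- data$PC_std
    cols$b_vc_pc <- data$VC_std * data$PC_std
  }
  if (data$model_kind == "mundlak") {
    cols$b_gun_bar <- data$G_bar_by_state[data$group_index]
  }
  do.call(cbind, cols)
}

# Data-informed, jittered starting point for one chain.
init_point <- function(data, model, jitter = 1) {
  S <- data$n_states
  rate_s <- (as.vector(rowsum(data$y, data$group_index)) + 0.5) /
    as.vector(rowsum(exp(data$log_offset), data$group_index))
  alpha0 <- log(rate_s)
  list(
    alpha = alpha0 + stats::rnorm(S, 0, 0.3 * jitter),
    alpha_bar = mean(alpha0) + stats::rnorm(1, 0, 0.5 * jitter),
    log_tau = log(stats::sd(alpha0) + 0.1) + stats::rnorm(1, 0, 0.3 * jitter),
    beta = stats::rnorm(length(beta_names(data$model_kind, data$adjusted)),
                        0, 0.1 * jitter),
    log_phi = if (is.null(model$fixed_phi)) {
      log(10) + stats::rnorm(1, 0, 0.5 * jitter)
    } else {
      log(model$fixed_phi)
    }
  )
}

# Per-observation NB log pmf with overflow guard; returns list(ll, bad).
obs_loglik <- function(y, eta, phi) {
  lam <- exp(eta)
  bad <- !is.finite(lam)
  if (any(bad)) lam[bad] <- 1
  ll <- stats::dnbinom(y, size = phi, mu = lam, log = TRUE)
  ll[bad | !is.finite(ll)] <- -Inf
  list(ll = ll, bad = any(bad))
}

run_chain <- function(data, model, cfg, chain_seed, init = NULL) {
  set.seed(chain_seed)
  pooled <- data$model_kind %in% c("mundlak", "random_intercept")
  sample_phi <- is.null(model$fixed_phi)
  S <- data$n_states
  X <- design_matrix(data)
  K <- ncol(X)
  y <- data$y
  g <- data$group_index

  # initialization: retry jittered starts until the posterior is finite
  th <- NULL
  for (attempt in 1:20) {
    cand <- if (!is.null(init) && attempt == 1) init else
      init_point(data, model, jitter = 1)
    params <- list(alpha_bar = cand$alpha_bar, tau = exp(cand$log_tau),
                   alpha = cand$alpha, beta = cand$beta,
                   phi = exp(cand$log_phi))
    lp <- log_posterior(data, params, model)
    if (is.finite(lp)) { th <- cand; break }
  }
  if (is.null(th)) {
    stop("initialization failure: log posterior non-finite at every ",
         "attempted starting point", call. = FALSE)
  }

  eta <- data$log_offset + th$alpha[g] + drop(X %*% th$beta)
  phi <- exp(th$log_phi)
  ll <- obs_loglik(y, eta, phi)$ll

  # ridge directions: the exposure column decomposed into its state means
  # and within-state deviations; the slope trades off against the state
  # intercepts (and, for Mundlak, against the group-mean slope) along these
  gbar_s <- as.vector(rowsum(data$G_std, g)) / tabulate(g, S)
  g_within <- data$G_std - gbar_s[g]
  mundlak <- data$model_kind == "mundlak"
  k_bar <- if (mundlak) K else NA_integer_

  # proposal scales: alpha block (per state), betas, ridge moves, hyperparams
  sc_alpha <- rep(0.1, S)
  sc_beta <- rep(0.05, K)
  sc_w <- 0.1; sc_b <- 0.1
  sc_ab <- 0.1; sc_lt <- 0.3; sc_lphi <- 0.2
  acc_alpha <- numeric(S); acc_beta <- numeric(K)
  acc_w <- 0; acc_b <- 0
  acc_ab <- 0; acc_lt <- 0; acc_lphi <- 0
  warnings_count <- 0L

  n_iter <- cfg$n_warmup + cfg$n_samples
  par_names <- c(if (pooled) c("alpha_bar", "tau"),
                 paste0("alpha[", seq_len(S), "]"),
                 colnames(X),
                 if (sample_phi) "phi",
                 "lp__")
  out <- matrix(NA_real_, nrow = cfg$n_samples, ncol = length(par_names),
                dimnames = list(NULL, par_names))

  for (iter in seq_len(n_iter)) {
    ## 1. state intercepts, proposed in parallel, accepted per state
    ##    (valid because the likelihood factorizes over states given the rest)
    delta <- stats::rnorm(S) * sc_alpha
    alpha_prop <- th$alpha + delta
    eta_prop <- eta + delta[g]
    lp_obs <- obs_loglik(y, eta_prop, phi)
    if (lp_obs$bad) warnings_count <- warnings_count + 1L
    dll <- as.vector(rowsum(lp_obs$ll - ll, g))
    dprior <- if (pooled) {
      stats::dnorm(alpha_prop, th$alpha_bar, exp(th$log_tau), log = TRUE) -
        stats::dnorm(th$alpha, th$alpha_bar, exp(th$log_tau), log = TRUE)
    } else {
      stats::dnorm(alpha_prop, model$alpha_bar_mean, model$alpha_bar_sd,
                   log = TRUE) -
        stats::dnorm(th$alpha, model$alpha_bar_mean, model$alpha_bar_sd,
                     log = TRUE)
    }
    logr_s <- dll + dprior
    acc <- !is.na(logr_s) & (log(stats::runif(S)) < logr_s)
    if (any(acc)) {
      th$alpha[acc] <- alpha_prop[acc]
      obs_acc <- acc[g]
      eta[obs_acc] <- eta_prop[obs_acc]
      ll[obs_acc] <- lp_obs$ll[obs_acc]
    }
    acc_alpha <- acc_alpha + acc

    ## 2. slopes, one scalar random-walk update each
    for (k in seq_len(K)) {
      d <- stats::rnorm(1) * sc_beta[k]
      eta_prop <- eta + X[, k] * d
      lp_obs <- obs_loglik(y, eta_prop, phi)
      if (lp_obs$bad) warnings_count <- warnings_count + 1L
      b_new <- th$beta[k] + d
      logr <- sum(lp_obs$ll) - sum(ll) +
        stats::dnorm(b_new, 0, model$beta_sd, log = TRUE) -
        stats::dnorm(th$beta[k], 0, model$beta_sd, log = TRUE)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        th$beta[k] <- b_new
        eta <- eta_prop
        ll <- lp_obs$ll
        acc_beta[k] <- acc_beta[k] + 1
      }
    }

    ## 2b. ridge move within/between (Mundlak): move exposure weight between
    ##     the observation-level slope and the group-mean slope
    if (mundlak) {
      d <- stats::rnorm(1) * sc_w
      eta_prop <- eta + d * g_within
      lp_obs <- obs_loglik(y, eta_prop, phi)
      logr <- sum(lp_obs$ll) - sum(ll) +
        stats::dnorm(th$beta[1] + d, 0, model$beta_sd, log = TRUE) -
        stats::dnorm(th$beta[1], 0, model$beta_sd, log = TRUE) +
        stats::dnorm(th$beta[k_bar] - d, 0, model$beta_sd, log = TRUE) -
        stats::dnorm(th$beta[k_bar], 0, model$beta_sd, log = TRUE)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        th$beta[1] <- th$beta[1] + d
        th$beta[k_bar] <- th$beta[k_bar] - d
        eta <- eta_prop
        ll <- lp_obs$ll
        acc_w <- acc_w + 1
      }
    }

    ## 2c. ridge move slope vs. state intercepts
    d <- stats::rnorm(1) * sc_b
    alpha_prop <- th$alpha - d * gbar_s
    tau_now <- exp(th$log_tau)
    dprior_alpha <- if (pooled) {
      sum(stats::dnorm(alpha_prop, th$alpha_bar, tau_now, log = TRUE)) -
        sum(stats::dnorm(th$alpha, th$alpha_bar, tau_now, log = TRUE))
    } else {
      sum(stats::dnorm(alpha_prop, model$alpha_bar_mean, model$alpha_bar_sd,
                       log = TRUE)) -
        sum(stats::dnorm(th$alpha, model$alpha_bar_mean, model$alpha_bar_sd,
                         log = TRUE))
    }
    if (mundlak) {
      # group-mean slope absorbs the shift: eta is unchanged exactly
      logr <- dprior_alpha +
        stats::dnorm(th$beta[k_bar] + d, 0, model$beta_sd, log = TRUE) -
        stats::dnorm(th$beta[k_bar], 0, model$beta_sd, log = TRUE)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        th$alpha <- alpha_prop
        th$beta[k_bar] <- th$beta[k_bar] + d
        acc_b <- acc_b + 1
      }
    } else {
      eta_prop <- eta + d * g_within
      lp_obs <- obs_loglik(y, eta_prop, phi)
      logr <- sum(lp_obs$ll) - sum(ll) + dprior_alpha +
        stats::dnorm(th$beta[1] + d, 0, model$beta_sd, log = TRUE) -
        stats::dnorm(th$beta[1], 0, model$beta_sd, log = TRUE)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        th$alpha <- alpha_prop
        th$beta[1] <- th$beta[1] + d
        eta <- eta_prop
        ll <- lp_obs$ll
        acc_b <- acc_b + 1
      }
    }

    if (pooled) {
      ## 3. grand intercept (prior + intercept terms only; no likelihood)
      tau <- exp(th$log_tau)
      ab_prop <- th$alpha_bar + stats::rnorm(1) * sc_ab
      logr <- stats::dnorm(ab_prop, model$alpha_bar_mean, model$alpha_bar_sd,
                           log = TRUE) -
        stats::dnorm(th$alpha_bar, model$alpha_bar_mean, model$alpha_bar_sd,
                     log = TRUE) +
        sum(stats::dnorm(th$alpha, ab_prop, tau, log = TRUE)) -
        sum(stats::dnorm(th$alpha, th$alpha_bar, tau, log = TRUE))
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        th$alpha_bar <- ab_prop
        acc_ab <- acc_ab + 1
      }

      ## 4. intercept scale on the log scale (Jacobian: + log_tau)
      lt_prop <- th$log_tau + stats::rnorm(1) * sc_lt
      tau_prop <- exp(lt_prop)
      logr <- stats::dexp(tau_prop, model$tau_rate, log = TRUE) + lt_prop -
        stats::dexp(tau, model$tau_rate, log = TRUE) - th$log_tau +
        sum(stats::dnorm(th$alpha, th$alpha_bar, tau_prop, log = TRUE)) -
        sum(stats::dnorm(th$alpha, th$alpha_bar, tau, log = TRUE))
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        th$log_tau <- lt_prop
        acc_lt <- acc_lt + 1
      }
    }

    ## 5. dispersion on the log scale
    if (sample_phi) {
      lphi_prop <- th$log_phi + stats::rnorm(1) * sc_lphi
      phi_prop <- exp(lphi_prop)
      lp_obs <- obs_loglik(y, eta, phi_prop)
      logr <- sum(lp_obs$ll) - sum(ll) +
        stats::dexp(phi_prop, model$phi_rate, log = TRUE) + lphi_prop -
        stats::dexp(phi, model$phi_rate, log = TRUE) - th$log_phi
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        th$log_phi <- lphi_prop
        phi <- phi_prop
        ll <- lp_obs$ll
        acc_lphi <- acc_lphi + 1
      }
    }

    ## warmup adaptation toward ~0.44 scalar acceptance
    if (iter <= cfg$n_warmup && iter %% cfg$adapt_window == 0) {
      w <- cfg$adapt_window
      sc_alpha <- sc_alpha * exp(acc_alpha / w - 0.44)
      sc_beta <- sc_beta * exp(acc_beta / w - 0.44)
      sc_w <- sc_w * exp(acc_w / w - 0.44)
      sc_b <- sc_b * exp(acc_b / w - 0.44)
      sc_ab <- sc_ab * exp(acc_ab / w - 0.44)
      sc_lt <- sc_lt * exp(acc_lt / w - 0.44)
      sc_lphi <- sc_lphi * exp(acc_lphi / w - 0.44)
      acc_alpha[] <- 0; acc_beta[] <- 0
      acc_w <- 0; acc_b <- 0
      acc_ab <- 0; acc_lt <- 0; acc_lphi <- 0
    }

    if (iter > cfg$n_warmup) {
      row <- iter - cfg$n_warmup
      lp <- sum(ll) + log_prior(
        list(alpha_bar = th$alpha_bar, tau = exp(th$log_tau),
             alpha = th$alpha, beta = th$beta, phi = phi),
        model
      )
      out[row, ] <- c(if (pooled) c(th$alpha_bar, exp(th$log_tau)),
                      th$alpha, th$beta, if (sample_phi) phi, lp)
    }
  }

  list(draws = out, warnings = warnings_count)
}

#' Draw posterior samples with the built-in adaptive Metropolis sampler
#'
#' Runs `n_chains` independent chains from overdispersed, jittered,
#' data-informed starting points. Identical seed, configuration, and data
#' give bit-identical draws. Constrained parameters are reported on their
#' natural (positive) scale; an `lp__` column records the unnormalized log
#' posterior of each kept draw.
#'
#' @param data A `model_data` from [build_model_data()].
#' @param model A [model_config()]; defaults to the standard priors for
#'   `data`'s variant.
#' @param sampler A [sampler_config()].
#' @param init Optional starting point for the first attempt of every chain
#'   (list with `alpha`, `alpha_bar`, `log_tau`, `beta`, `log_phi`).
#' @return A `posterior_draws` object: `draws` array indexed
#'   (chain, iteration, parameter), `parameter_names`, `sampler_warnings`
#'   (count of overflowing proposals), and the configurations used.
#' @export
sample_posterior <- function(data, model = NULL, sampler = sampler_config(),
                             init = NULL) {
  if (is.null(model)) {
    model <- model_config(data$model_kind, data$adjusted)
  }
  if (model$model_kind != data$model_kind || model$adjusted != data$adjusted) {
    stop("configuration error: model config does not match model data",
         call. = FALSE)
  }
  if (identical(sampler$backend, "external")) {
    return(sample_posterior_jags(data, model, sampler))
  }
  set.seed(sampler$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, sampler$n_chains)
  chains <- lapply(seq_len(sampler$n_chains), function(ch) {
    run_chain(data, model, sampler, chain_seeds[ch], init = init)
  })
  par_names <- colnames(chains[[1]]$draws)
  draws <- array(
    NA_real_,
    dim = c(sampler$n_chains, sampler$n_samples, length(par_names)),
    dimnames = list(NULL, NULL, par_names)
  )
  for (ch in seq_len(sampler$n_chains)) {
    draws[ch, , ] <- chains[[ch]]$draws
  }
  structure(
    list(
      draws = draws,
      parameter_names = par_names,
      sampler_warnings = sum(vapply(chains, `[[`, integer(1), "warnings")),
      config = sampler,
      model = model
    ),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("<posterior_draws> ", d[1], " chains x ", d[2], " iterations x ",
      d[3], " parameters\n", sep = "")
  invisible(x)
}

#' Extract the draws of one parameter as a chain-by-iteration matrix
#'
#' @param posterior A `posterior_draws` object.
#' @param parameter Parameter name (see `posterior$parameter_names`).
#' @return Numeric matrix with one row per chain.
#' @export
parameter_draws <- function(posterior, parameter) {
  if (!(parameter %in% posterior$parameter_names)) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  posterior$draws[, , parameter, drop = TRUE]
}
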