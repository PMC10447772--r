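#' @keywords internal
#' JAGS (Gibbs sampling) backend for sample_posterior().
#'
#' The Gamma-Poisson likelihood is written as the explicit Poisson-Gamma
#' mixture (y ~ Poisson(lambda * g), g ~ Gamma(phi, phi)) so the shape phi
#' can be real-valued. Parameter names and the draws layout match the
#' built-in backend; tau and phi are returned on the natural scale.
jags_model_string <- function(data, model) {
  pooled <- data$model_kind %in% c("mundlak", "random_intercept")
  lin <- "log_offset[i] + alpha[state[i]] + inprod(X[i, ], beta)"
  paste0(
    "model {\n",
    "  for (i in 1:n) {\n",
    "    g[i] ~ dgamma(phi, phi)\n",
    "    y[i] ~ dpois(exp(", lin, ") * g[i])\n",
    "  }\n",
    if (pooled) paste0(
      "  for (s in 1:S) { alpha[s] ~ dnorm(alpha_bar, 1 / (tau * tau)) }\n",
      "  alpha_bar ~ dnorm(", model$alpha_bar_mean, ", ",
      1 / model$alpha_bar_sd^2, ")\n",
      "  tau ~ dexp(", model$tau_rate, ")\n"
    ) else paste0(
      "  for (s in 1:S) { alpha[s] ~ dnorm(", model$alpha_bar_mean, ", ",
      1 / model$alpha_bar_sd^2, ") }\n"
    ),
    "  for (k in 1:K) { beta[k] ~ dnorm(0, ", 1 / model$beta_sd^2, ") }\n",
    if (is.null(model$fixed_phi)) {
      paste0("  phi ~ dexp(", model$phi_rate, ")\n")
    } else {
      ""
    },
    "}\n"
  )
}

sample_posterior_jags <- function(data, model, sampler) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("the external backend requires the rjags package", call. = FALSE)
  }
  pooled <- data$model_kind %in% c("mundlak", "random_intercept")
  sample_phi <- is.null(model$fixed_phi)
  X <- design_matrix(data)
  jdata <- list(
    y = data$y, log_offset = data$log_offset, state = data$group_index,
    X = X, n = data$n, S = data$n_states, K = ncol(X)
  )
  if (!sample_phi) jdata$phi <- model$fixed_phi

  set.seed(sampler$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, sampler$n_chains)
  inits <- lapply(chain_seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })

  monitored <- c(if (pooled) c("alpha_bar", "tau"), "alpha", "beta",
                 if (sample_phi) "phi")
  jm <- rjags::jags.model(textConnection(jags_model_string(data, model)),
                          data = jdata, inits = inits,
                          n.chains = sampler$n_chains,
                          n.adapt = max(sampler$n_warmup, 100), quiet = TRUE)
  stats::update(jm, n.iter = sampler$n_warmup, progress.bar = "none")
  cs <- rjags::coda.samples(jm, monitored, n.iter = sampler$n_samples,
                            progress.bar = "none")

  bnames <- colnames(X)
  par_names <- c(if (pooled) c("alpha_bar", "tau"),
                 paste0("alpha[", seq_len(data$n_states), "]"),
                 bnames,
                 if (sample_phi) "phi")
  draws <- array(
    NA_real_,
    dim = c(sampler$n_chains, sampler$n_samples, length(par_names)),
    dimnames = list(NULL, NULL, par_names)
  )
  for (ch in seq_len(sampler$n_chains)) {
    m <- as.matrix(cs[[ch]])
    jbeta <- paste0("beta[", seq_along(bnames), "]")
    if (length(bnames) == 1 && !"beta[1]" %in% colnames(m)) jbeta <- "beta"
    colnames(m)[match(jbeta, colnames(m))] <- bnames
    if (data$n_states == 1 && "alpha" %in% colnames(m)) {
      colnames(m)[colnames(m) == "alpha"] <- "alpha[1]"
    }
    draws[ch, , ] <- m[, par_names]
  }
  structure(
    list(draws = draws, parameter_names = par_names,
         sampler_warnings = 0L, config = sampler, model = model),
    class = "posterior_draws"
  )
}
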