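# Hand-assembled model_data for unit tests that need exact covariate values
# (build_model_data always standardizes, which these tests bypass on purpose).
toy_model_data <- function(y, log_offset, group_index, G_std,
                           VC_std = NULL, PC_std = NULL,
                           G_bar_by_state = NULL,
                           model_kind = "fixed_effects", adjusted = FALSE) {
  n_states <- max(group_index)
  structure(
    list(
      y = as.integer(y), log_offset = log_offset,
      group_index = as.integer(group_index),
      state_levels = as.character(seq_len(n_states)),
      G_std = G_std, VC_std = VC_std, PC_std = PC_std,
      G_bar_by_state = G_bar_by_state,
      standardization = list(),
      model_kind = model_kind, adjusted = adjusted,
      n = length(y), n_states = n_states
    ),
    class = "model_data"
  )
}

# posterior_draws object with prescribed per-parameter draws (recycled),
# for summary/predictive tests that need a point or fixed posterior.
fake_posterior <- function(values, n_chains = 2, n_iter = 50, model = NULL) {
  par_names <- names(values)
  draws <- array(
    NA_real_, dim = c(n_chains, n_iter, length(par_names)),
    dimnames = list(NULL, NULL, par_names)
  )
  for (p in par_names) {
    draws[, , p] <- matrix(rep_len(values[[p]], n_chains * n_iter),
                           n_chains, n_iter)
  }
  structure(
    list(draws = draws, parameter_names = par_names,
         sampler_warnings = 0L,
         config = sampler_config(n_chains, 0, n_iter),
         model = if (is.null(model)) model_config() else model),
    class = "posterior_draws"
  )
}

# Brute-force shortest-window HPDI used as the independent oracle.
hpdi_brute <- function(x, mass = 0.89) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < best[1]) best <- c(w, s[i], s[i + m - 1])
  }
  c(best[2], best[3])
}

# Small deterministic panel: 2 states x 2 years with easy numbers.
toy_panel <- function() {
  tibble::tibble(
    state = c("A", "A", "B", "B"),
    year = c(2000L, 2001L, 2000L, 2001L),
    deaths = c(10L, 12L, 30L, 28L),
    population = c(1e6, 1e6, 2e6, 2e6),
    gun_ownership = c(30, 32, 50, 52),
    violent_crime_rate = c(300, 310, 500, 490),
    property_crime_rate = c(2500, 2550, 3500, 3450)
  )
}
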