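#' Incidence rate ratio from a log-scale coefficient
#'
#' Exponentiates a posterior-mean coefficient on the log-rate scale into the
#' multiplicative incidence rate ratio (IRR) and the percent change in the
#' event rate per one standard deviation of the exposure (the design is
#' standardized, so coefficients are already per-SD). The percent change is
#' kept at full precision; `display` rounds to integer percent for
#' reporting.
#'
#' @param beta_mean Posterior mean of the coefficient (log-rate scale,
#'   per 1 SD of exposure).
#' @param exposure_sd_original_units Optional annotation: the exposure SD in
#'   its original units (percentage points of household gun ownership).
#' @return An `irr_report` list: `coefficient_mean`, `irr`, `percent_change`,
#'   `exposure_sd_original_units`, and `display` (e.g. `"6%"`).
#' @examples
#' irr_from_coefficient(0.06)$display # "6%"
#' @export
irr_from_coefficient <- function(beta_mean, exposure_sd_original_units = NA_real_) {
  if (!is.finite(beta_mean)) stop("beta_mean must be finite", call. = FALSE)
  irr <- exp(beta_mean)
  pct <- (irr - 1) * 100
  structure(
    list(
      coefficient_mean = beta_mean,
      irr = irr,
      percent_change = pct,
      exposure_sd_original_units = exposure_sd_original_units,
      display = paste0(round(pct), "%")
    ),
    class = "irr_report"
  )
}

#' @export
print.irr_report <- function(x, ...) {
  cat("IRR ", format(x$irr, digits = 4), " (", x$display,
      " change per 1 SD of exposure", sep = "")
  if (is.finite(x$exposure_sd_original_units)) {
    cat(", SD = ", x$exposure_sd_original_units, " percentage points", sep = "")
  }
  cat(")\n")
  invisible(x)
}

#' Posterior predictive simulation of the panel counts
#'
#' For each of `n_draws` posterior draws (evenly thinned over the pooled
#' chains), reconstructs the expected count of every observation through the
#' linear predictor and simulates a Gamma-Poisson count at the draw's
#' dispersion. Seedable and reproducible.
#'
#' @param posterior A `posterior_draws` object.
#' @param data The `model_data` the posterior was fit to.
#' @param n_draws Number of posterior draws to simulate from (at most the
#'   number available).
#' @param seed Integer seed for the simulation.
#' @return A `predictive_sample` list: `simulated_counts` (matrix draw x
#'   observation) and `observed_counts`.
#' @export
posterior_predictive <- function(posterior, data, n_draws = 200, seed = 1) {
  d <- dim(posterior$draws)
  total <- d[1] * d[2]
  if (n_draws > total) {
    stop("configuration error: n_draws exceeds available posterior draws",
         call. = FALSE)
  }
  pooled <- data$model_kind %in% c("mundlak", "random_intercept")
  flat <- matrix(aperm(posterior$draws, c(2, 1, 3)), nrow = total,
                 dimnames = list(NULL, posterior$parameter_names))
  pick <- unique(round(seq(1, total, length.out = n_draws)))

  alpha_cols <- paste0("alpha[", seq_len(data$n_states), "]")
  bnames <- beta_names(data$model_kind, data$adjusted)
  fixed_phi <- posterior$model$fixed_phi

  set.seed(seed)
  sims <- matrix(NA_integer_, nrow = length(pick), ncol = data$n)
  for (i in seq_along(pick)) {
    row <- flat[pick[i], ]
    params <- list(
      alpha_bar = if (pooled) row[["alpha_bar"]],
      tau = if (pooled) row[["tau"]],
      alpha = unname(row[alpha_cols]),
      beta = unname(row[bnames]),
      phi = if (is.null(fixed_phi)) row[["phi"]] else fixed_phi
    )
    lam <- exp(linear_predictor(data, params))
    sims[i, ] <- stats::rnbinom(data$n, size = params$phi, mu = lam)
  }
  structure(
    list(simulated_counts = sims, observed_counts = data$y),
    class = "predictive_sample"
  )
}

#' Pointwise predictive-interval coverage of the observed counts
#'
#' Fraction of observations whose observed count falls inside the pointwise
#' HPDI of its simulated predictive counts at the given mass.
#'
#' @param pred A `predictive_sample` from [posterior_predictive()].
#' @param mass Interval mass; default 0.89.
#' @return Scalar coverage fraction in \[0, 1\].
#' @export
predictive_coverage <- function(pred, mass = 0.89) {
  n <- length(pred$observed_counts)
  inside <- vapply(seq_len(n), function(j) {
    iv <- hpdi(pred$simulated_counts[, j], mass)
    pred$observed_counts[j] >= iv$lower && pred$observed_counts[j] <= iv$upper
  }, logical(1))
  mean(inside)
}

#' Kernel density summary of a posterior marginal
#'
#' Gaussian kernel density on a regular grid spanning the draw range
#' (extended by three bandwidths so the density integrates to one), with
#' Silverman's rule-of-thumb bandwidth by default.
#'
#' @param posterior A `posterior_draws` object, or a numeric vector of draws.
#' @param parameter Parameter name (ignored when `posterior` is a vector).
#' @param grid_size Number of grid points.
#' @param bw Bandwidth; default Silverman's rule (`"nrd0"`).
#' @return List with `grid`, `density`, and `point_mass` (TRUE when the
#'   draws are degenerate, in which case `grid`/`density` are a single spike
#'   location and `Inf`).
#' @export
density_summary <- function(posterior, parameter = NULL, grid_size = 512,
                            bw = "nrd0") {
  x <- if (is.numeric(posterior)) as.vector(posterior) else
    as.vector(parameter_draws(posterior, parameter))
  if (stats::sd(x) == 0) {
    return(list(grid = x[1], density = Inf, point_mass = TRUE))
  }
  bw_val <- if (is.character(bw)) stats::bw.nrd0(x) else bw
  d <- stats::density(x, bw = bw_val, n = grid_size,
                      from = min(x) - 3 * bw_val, to = max(x) + 3 * bw_val)
  list(grid = d$x, density = d$y, point_mass = FALSE)
}

#' Forest-table of coefficient estimates across models
#'
#' Assembles the per-model reporting rows (label, posterior mean, interval
#' bounds) into one machine-readable table, flagging intervals that straddle
#' zero.
#'
#' @param summaries Non-empty list; each element a list with `label`, `mean`,
#'   and `interval` (a list with `lower`/`upper`, as from [hpdi()]).
#' @return Tibble with `label`, `mean`, `lower`, `upper`, `includes_zero`.
#' @export
forest_table <- function(summaries) {
  if (length(summaries) == 0) {
    stop("forest_table needs at least one entry", call. = FALSE)
  }
  rows <- lapply(summaries, function(s) {
    tibble::tibble(
      label = s$label,
      mean = s$mean,
      lower = s$interval$lower,
      upper = s$interval$upper,
      includes_zero = s$interval$lower <= 0 && s$interval$upper >= 0
    )
  })
  do.call(rbind, rows)
}

#' Forest plot of coefficient estimates
#'
#' @param table A tibble from [forest_table()].
#' @return A ggplot object.
#' @export
forest_plot <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("forest_plot requires ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(
    table,
    ggplot2::aes(x = .data$mean, y = .data$label,
                 xmin = .data$lower, xmax = .data$upper)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::labs(x = "Coefficient (log rate per 1 SD of exposure), 89% HPDI",
                  y = NULL) +
    ggplot2::theme_minimal()
}
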