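#' Read and validate a state-year panel from CSV
#'
#' Reads a CSV with one row per state-year observation and validates it
#' against the panel contract: non-negative integer death counts, strictly
#' positive populations, gun ownership in \[0, 100\] percent, non-negative
#' crime rates, and unique (state, year) pairs.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Named character vector (or list) mapping the canonical
#'   column names (`state`, `year`, `deaths`, `population`, `gun_ownership`,
#'   `violent_crime_rate`, `property_crime_rate`) to the column names used in
#'   the file. Canonical names missing from the mapping are looked up
#'   verbatim.
#'
#' @return A `panel_table`: a [tibble::tibble] with the seven canonical
#'   columns and attributes `n_states` and `n_years`. Unbalanced panels are
#'   accepted with a warning.
#'
#' @examples
#' path <- system.file("extdata", "toy_panel.csv", package = "gppanel")
#' panel <- load_panel(path)
#' nrow(panel)
#' @export
load_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop("panel file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)

  canonical <- c(
    "state", "year", "deaths", "population",
    "gun_ownership", "violent_crime_rate", "property_crime_rate"
  )
  mapping <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) {
    schema <- unlist(schema)
    unknown <- setdiff(names(schema), canonical)
    if (length(unknown) > 0) {
      stop("schema maps unknown canonical columns: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mapping[names(schema)] <- schema
  }
  missing_cols <- mapping[!(mapping %in% names(raw))]
  if (length(missing_cols) > 0) {
    stop("schema error: column(s) not present in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  panel <- tibble::tibble(
    state               = as.character(raw[[mapping[["state"]]]]),
    year                = as.integer(raw[[mapping[["year"]]]]),
    deaths              = raw[[mapping[["deaths"]]]],
    population          = raw[[mapping[["population"]]]],
    gun_ownership       = raw[[mapping[["gun_ownership"]]]],
    violent_crime_rate  = raw[[mapping[["violent_crime_rate"]]]],
    property_crime_rate = raw[[mapping[["property_crime_rate"]]]]
  )
  as_panel_table(panel)
}

#' Construct a validated panel table
#'
#' Validates a data frame of state-year records and attaches panel metadata.
#' Reported validation failures name the offending rows.
#'
#' @param panel Data frame with columns `state`, `year`, `deaths`,
#'   `population`, `gun_ownership`, `violent_crime_rate`,
#'   `property_crime_rate`.
#' @return A `panel_table` tibble with attributes `n_states`, `n_years`, and
#'   `balanced`.
#' @export
as_panel_table <- function(panel) {
  required <- c(
    "state", "year", "deaths", "population",
    "gun_ownership", "violent_crime_rate", "property_crime_rate"
  )
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  panel <- tibble::as_tibble(panel[required])

  numeric_cols <- setdiff(required, "state")
  for (col in numeric_cols) {
    if (!is.numeric(panel[[col]])) {
      stop("validation error: column '", col, "' is not numeric", call. = FALSE)
    }
  }

  bad <- function(cond) which(is.na(cond) | cond)
  problems <- list(
    "deaths is missing, negative, or non-integer" =
      bad(is.na(panel$deaths) | panel$deaths < 0 |
            panel$deaths != round(panel$deaths)),
    "population is missing or not positive" =
      bad(is.na(panel$population) | panel$population <= 0),
    "gun_ownership outside [0, 100]" =
      bad(is.na(panel$gun_ownership) | panel$gun_ownership < 0 |
            panel$gun_ownership > 100),
    "violent_crime_rate is missing or negative" =
      bad(is.na(panel$violent_crime_rate) | panel$violent_crime_rate < 0),
    "property_crime_rate is missing or negative" =
      bad(is.na(panel$property_crime_rate) | panel$property_crime_rate < 0)
  )
  problems <- problems[vapply(problems, length, integer(1)) > 0]
  if (length(problems) > 0) {
    msgs <- vapply(
      names(problems),
      function(nm) paste0(nm, " (row ", paste(problems[[nm]], collapse = ", "), ")"),
      character(1)
    )
    stop("validation error: ", paste(msgs, collapse = "; "), call. = FALSE)
  }

  key <- paste(panel$state, panel$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("validation error: duplicate (state, year) pairs (row ",
         paste(dup, collapse = ", "), ")", call. = FALSE)
  }

  n_states <- length(unique(panel$state))
  n_years <- length(unique(panel$year))
  balanced <- nrow(panel) == n_states * n_years
  if (!balanced) {
    warning("panel is unbalanced: ", nrow(panel), " records != ",
            n_states, " states x ", n_years, " years", call. = FALSE)
  }
  structure(
    panel,
    n_states = n_states, n_years = n_years, balanced = balanced,
    class = c("panel_table", class(panel))
  )
}

#' Standardize a numeric vector to mean zero and unit standard deviation
#'
#' Centering and scaling use the sample mean and the `n - 1` denominator
#' standard deviation, pooled over all supplied values. The returned
#' parameters invert the transform via [unstandardize()].
#'
#' @param x Numeric vector, length at least 2, with positive variance.
#' @return List with `z` (the standardized vector) and `params`, a list
#'   holding `mean` and `sd` in the original units.
#' @export
standardize <- function(x) {
  if (length(x) < 2) {
    stop("standardize requires at least 2 values", call. = FALSE)
  }
  if (anyNA(x)) stop("standardize: input contains NA", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate variance: cannot standardize a constant vector",
         call. = FALSE)
  }
  list(z = (x - m) / s, params = list(mean = m, sd = s))
}

#' Invert a standardization
#'
#' @param z Standardized values.
#' @param params `mean`/`sd` list returned by [standardize()].
#' @return Values on the original scale.
#' @export
unstandardize <- function(z, params) {
  z * params$sd + params$mean
}

#' Per-group means of a vector
#'
#' Arithmetic mean of `values` within each group, used to form the group-mean
#' exposure covariate of the Mundlak device.
#'
#' @param values Numeric vector.
#' @param group_index Integer vector of the same length with values in
#'   `1:n_groups`.
#' @param n_groups Number of groups; every group must have at least one
#'   observation.
#' @return Numeric vector of length `n_groups`.
#' @export
compute_state_means <- function(values, group_index, n_groups) {
  if (length(values) != length(group_index)) {
    stop("values and group_index must be aligned", call. = FALSE)
  }
  counts <- tabulate(group_index, nbins = n_groups)
  if (any(counts == 0)) {
    stop("missing-group error: group(s) with no observations: ",
         paste(which(counts == 0), collapse = ", "), call. = FALSE)
  }
  sums <- as.vector(rowsum(values, group_index, reorder = TRUE))
  sums / counts
}

#' Assemble model-ready design arrays from a panel
#'
#' Pools the standardization of gun ownership and both crime rates over all
#' state-years, computes the log-population offset, indexes states, and (for
#' the Mundlak variant) adds the per-state mean of the standardized exposure.
#' The interaction of the two crime rates is the product of the standardized
#' series.
#'
#' @param panel A `panel_table` (see [load_panel()], [as_panel_table()]).
#' @param model_kind One of `"mundlak"` (random intercepts plus the state
#'   mean of the exposure), `"fixed_effects"` (free per-state intercepts), or
#'   `"random_intercept"` (random intercepts without the group-mean term — a
#'   deliberately naive specification kept for confounding-bias studies).
#' @param adjusted Logical; include the crime-rate covariates and their
#'   interaction (`TRUE`, default) or the exposure alone (`FALSE`).
#' @return A `model_data` list with fields `y`, `log_offset`, `group_index`,
#'   `state_levels`, `G_std`, `VC_std`, `PC_std`, `G_bar_by_state`,
#'   `standardization` (per-variable mean/sd), `model_kind`, `adjusted`,
#'   `n`, and `n_states`.
#' @export
build_model_data <- function(panel,
                             model_kind = c("mundlak", "fixed_effects",
                                            "random_intercept"),
                             adjusted = TRUE) {
  model_kind <- match.arg(model_kind)
  panel <- as_panel_table(panel)

  state_levels <- sort(unique(panel$state))
  group_index <- match(panel$state, state_levels)
  n_states <- length(state_levels)

  g <- standardize(panel$gun_ownership)
  std <- list(gun_ownership = g$params)
  vc_std <- pc_std <- NULL
  if (adjusted) {
    vc <- standardize(panel$violent_crime_rate)
    pc <- standardize(panel$property_crime_rate)
    vc_std <- vc$z
    pc_std <- pc$z
    std$violent_crime_rate <- vc$params
    std$property_crime_rate <- pc$params
  }

  g_bar <- NULL
  if (model_kind == "mundlak") {
    g_bar <- compute_state_means(g$z, group_index, n_states)
  }

  structure(
    list(
      y = as.integer(panel$deaths),
      log_offset = log(panel$population),
      group_index = group_index,
      state_levels = state_levels,
      G_std = g$z,
      VC_std = vc_std,
      PC_std = pc_std,
      G_bar_by_state = g_bar,
      standardization = std,
      model_kind = model_kind,
      adjusted = adjusted,
      n = nrow(panel),
      n_states = n_states
    ),
    class = "model_data"
  )
}

#' @export
print.model_data <- function(x, ...) {
  cat("<model_data> ", x$n, " observations, ", x$n_states, " states\n",
      "  model_kind: ", x$model_kind,
      ", adjusted: ", x$adjusted, "\n", sep = "")
  invisible(x)
}

#' Serialize a model-data summary to JSON
#'
#' Writes the reproducibility log for a design: dimensions, configuration,
#' standardization parameters, and a digest of the response.
#'
#' @param data A `model_data` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_model_data_summary <- function(data, path) {
  summary <- list(
    n = data$n,
    n_states = data$n_states,
    model_kind = data$model_kind,
    adjusted = data$adjusted,
    standardization = data$standardization,
    y_total = sum(data$y),
    y_median = stats::median(data$y)
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
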