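test_that("load_panel round-trips a well-formed CSV and honours schema maps", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(toy_panel()[1:3, ], path, row.names = FALSE)
  expect_warning(panel <- load_panel(path), "unbalanced")
  expect_s3_class(panel, "panel_table")
  expect_equal(nrow(panel), 3)
  expect_equal(panel$deaths, c(10L, 12L, 30L))

  # renamed columns resolved through the schema mapping
  renamed <- toy_panel()
  names(renamed)[names(renamed) == "deaths"] <- "fatalities"
  names(renamed)[names(renamed) == "state"] <- "st"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(renamed, path2, row.names = FALSE)
  expect_error(load_panel(path2), "schema error")
  panel2 <- load_panel(path2, schema = c(deaths = "fatalities", state = "st"))
  expect_equal(panel2$deaths, toy_panel()$deaths)
})

test_that("invalid records are rejected with their row numbers", {
  bad <- toy_panel()
  bad$deaths[2] <- -1
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(load_panel(path), "row 2")

  dup <- toy_panel()
  dup$year[2] <- dup$year[1]
  expect_error(as_panel_table(dup), "duplicate")

  oob <- toy_panel()
  oob$gun_ownership[4] <- 130
  expect_error(as_panel_table(oob), "row 4")

  unbalanced <- toy_panel()[1:3, ]
  expect_warning(as_panel_table(unbalanced), "unbalanced")
})

test_that("a 50-state x 18-year panel written to CSV reloads with 900 records", {
  sim <- simulate_panel(generator_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(sim$panel), path, row.names = FALSE)
  panel <- load_panel(path)
  expect_equal(nrow(panel), 900)
  expect_equal(attr(panel, "n_states"), 50)
  expect_equal(attr(panel, "n_years"), 18)
  expect_true(attr(panel, "balanced"))
})

test_that("standardize matches the direct formula and inverts exactly", {
  z3 <- standardize(c(1, 2, 3))
  expect_equal(mean(z3$z), 0)
  expect_equal(stats::sd(z3$z), 1)
  expect_equal(z3$params$mean, 2)
  expect_equal(z3$z[1], -1)

  expect_error(standardize(c(5, 5, 5)), "degenerate variance")
  expect_error(standardize(3), "at least 2")

  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  got <- standardize(x)
  # element-by-element oracle from the defining formula
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_equal(got$z, (x - m) / s, tolerance = 1e-12)
  expect_equal(unstandardize(got$z, got$params), x, tolerance = 1e-9)
})

test_that("compute_state_means equals a per-group loop", {
  expect_equal(compute_state_means(c(1, 2, 3), c(1, 1, 1), 1), 2)
  expect_equal(compute_state_means(c(0, 0, 10, 10), c(1, 1, 2, 2), 2),
               c(0, 10))
  expect_error(compute_state_means(c(1, 2), c(1, 1), 2), "missing-group")

  set.seed(42)
  values <- rnorm(60)
  groups <- sample(1:5, 60, replace = TRUE)
  oracle <- vapply(1:5, function(s) mean(values[groups == s]), numeric(1))
  expect_equal(compute_state_means(values, groups, 5), oracle)
})

test_that("build_model_data assembles the design exactly", {
  panel <- toy_panel()
  md <- build_model_data(panel, "mundlak", adjusted = TRUE)

  g <- panel$gun_ownership
  z <- (g - mean(g)) / stats::sd(g)
  expect_equal(md$G_std, z, tolerance = 1e-12)
  expect_lt(abs(mean(md$G_std)), 1e-10)
  expect_lt(abs(stats::sd(md$G_std) - 1), 1e-10)
  expect_lt(abs(mean(md$VC_std)), 1e-10)
  expect_lt(abs(stats::sd(md$PC_std) - 1), 1e-10)
  expect_equal(md$log_offset, log(panel$population))
  expect_equal(md$G_bar_by_state, c(mean(z[1:2]), mean(z[3:4])))

  # weighted grand mean of state means recovers the zero pooled mean
  sizes <- tabulate(md$group_index)
  expect_lt(abs(sum(md$G_bar_by_state * sizes) / sum(sizes)), 1e-10)

  fe <- build_model_data(panel, "fixed_effects", adjusted = TRUE)
  expect_null(fe$G_bar_by_state)
  expect_equal(fe$G_std, md$G_std)

  un <- build_model_data(panel, "mundlak", adjusted = FALSE)
  expect_null(un$VC_std)
  expect_null(un$PC_std)

  # deterministic: identical input gives identical output
  expect_identical(md, build_model_data(panel, "mundlak", adjusted = TRUE))
})
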