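test_that("a perfect line is recovered exactly", {
  wells <- tibble::tibble(puncta_per_cell = 0:5,
                          foci_per_cell = 2 * (0:5) + 1)
  fit <- fit_mechanism(wells)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_identical(fit$n_points, 6L)
})

test_that("OLS estimates match the closed-form normal equations to 1e-10", {
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- sample(3:20, 1)
      x <- c(0, runif(n - 1, 0, 30))  # include a blocker-style anchor
      y <- 0.4 * x + 1.2 + rnorm(n, 0, 0.3)
      fit <- fit_mechanism(tibble::tibble(puncta_per_cell = x, foci_per_cell = y))
      co <- ols_closed_form(x, y)
      expect_equal(fit$slope, unname(co["slope"]), tolerance = 1e-10)
      expect_equal(fit$intercept, unname(co["intercept"]), tolerance = 1e-10)
    }
  })
})

test_that("generated panels are recovered within two standard errors", {
  lib <- tibble::tibble(compound = "A", pka = 5.5, colloid_efficiency = 0.3,
                        free_drug_rate = 1.5, phospholipidosis_rate = 1)
  pan <- simulate_mechanism_panel(
    panel_spec(lib, wells_per_compound = 15, noise_sd = 0.1, seed = 19))
  fit <- fit_mechanism(pan)
  expect_lte(abs(fit$slope - 0.3), 2 * fit$slope_se)
  expect_lte(abs(fit$intercept - 1.5), 2 * fit$intercept_se)
})

test_that("degenerate designs (no uptake variation) raise the dedicated error", {
  all_zero <- tibble::tibble(puncta_per_cell = rep(0, 6),
                             foci_per_cell = rnorm(6, 1.5, 0.1))
  expect_error(fit_mechanism(all_zero), "uptake has no variation",
               class = "colloidquant_degenerate_design")
  expect_error(fit_mechanism(all_zero[1:2, ]), class = "colloidquant_bad_input")
})

test_that("including blocker anchors does not inflate the intercept SE", {
  lib <- tibble::tibble(compound = "A", pka = 6, colloid_efficiency = 0.2,
                        free_drug_rate = 1, phospholipidosis_rate = 0.5)
  worse <- 0
  for (s in 1:10) {
    pan <- simulate_mechanism_panel(
      panel_spec(lib, wells_per_compound = 20, blocker_fraction = 0.25,
                 noise_sd = 0.1, seed = 600 + s))
    with_b <- fit_mechanism(pan)
    without_b <- fit_mechanism(dplyr::filter(pan, !blocker))
    if (with_b$intercept_se > without_b$intercept_se) worse <- worse + 1
  }
  expect_identical(worse, 0)
})

test_that("panel-level fitting returns one row per compound", {
  lib <- simulate_compound_library(n_compounds = 4, seed = 3)
  pan <- simulate_mechanism_panel(panel_spec(lib, seed = 3))
  fits <- fit_mechanism_panel(pan)
  expect_identical(nrow(fits), 4L)
  expect_setequal(fits$compound, lib$compound)
  expect_true(all(fits$n_points == 15))
  expect_true(all(fits$r_squared >= 0 & fits$r_squared <= 1))
})

test_that("correlation is +/-1 under affine maps and invariant to rescaling", {
  base <- tibble::tibble(
    compound = sprintf("C%d", 1:6),
    slope = c(1, 3, 2, 5, 4, 6),
    intercept = c(1, 3, 2, 5, 4, 6),
    vesicles_per_cell = 2 * c(1, 3, 2, 5, 4, 6) + 7  # positive affine map
  )
  expect_equal(correlate_mechanism(base, "intercept")$r, 1, tolerance = 1e-12)
  neg <- dplyr::mutate(base, vesicles_per_cell = -3 * intercept + 10)
  expect_equal(correlate_mechanism(neg, "intercept")$r, -1, tolerance = 1e-12)

  withr::with_seed(5, {
    rnd <- dplyr::mutate(base, vesicles_per_cell = runif(6))
  })
  r0 <- correlate_mechanism(rnd, "efficiency")$r
  scaled <- dplyr::mutate(rnd, slope = 100 * slope - 4,
                          vesicles_per_cell = 0.01 * vesicles_per_cell + 2)
  expect_lt(abs(correlate_mechanism(scaled, "efficiency")$r - r0), 1e-12)

  expect_error(correlate_mechanism(base[1:2, ], "intercept"),
               class = "colloidquant_bad_input")
  flat <- dplyr::mutate(base, vesicles_per_cell = 1)
  expect_error(correlate_mechanism(flat, "intercept"),
               class = "colloidquant_bad_input")
})

test_that("a latent-driver library reproduces the two-mechanism correlation pattern", {
  lib <- simulate_compound_library(n_compounds = 15, seed = 7)
  pan <- simulate_mechanism_panel(panel_spec(lib, seed = 7))
  mech <- fit_mechanism_panel(pan)
  phospho <- pan |>
    dplyr::group_by(compound) |>
    dplyr::summarise(vesicles_per_cell = mean(vesicles_per_cell))
  sm <- build_compound_summary(mech, dplyr::select(lib, compound, pka), phospho)
  expect_gt(correlate_mechanism(sm, "intercept")$r, 0.9)
  expect_lt(abs(correlate_mechanism(sm, "efficiency")$r), 0.3)
})

test_that("compound summaries join shared ids and report missing ones", {
  mech <- tibble::tibble(compound = c("A", "B"), slope = 1:2, slope_se = 0.1,
                         intercept = 3:4, intercept_se = 0.1,
                         r_squared = 0.9, n_points = 15L)
  pka <- tibble::tibble(compound = c("A", "B", "C"), pka = c(5, 6, 7))
  ph <- tibble::tibble(compound = c("A", "B"), vesicles_per_cell = c(0.5, 1))

  expect_message(sm <- build_compound_summary(mech, pka, ph), "C")
  expect_identical(nrow(sm), 2L)
  expect_setequal(unique(attr(sm, "missing")$compound), "C")

  # disjoint ids: empty summary, all ids reported
  ph2 <- tibble::tibble(compound = c("X", "Y"), vesicles_per_cell = 1)
  expect_message(sm2 <- build_compound_summary(mech, pka, ph2))
  expect_identical(nrow(sm2), 0L)
  expect_setequal(unique(attr(sm2, "missing")$compound),
                  c("A", "B", "C", "X", "Y"))

  # single compound in all inputs: one row
  sm3 <- suppressMessages(
    build_compound_summary(mech[1, ], pka[1, ], ph[1, ]))
  expect_identical(nrow(sm3), 1L)

  dup <- dplyr::bind_rows(mech, mech[1, ])
  expect_error(build_compound_summary(dup, pka, ph),
               class = "colloidquant_bad_input")
})

test_that("tidy and glance methods expose estimates in broom shape", {
  wells <- tibble::tibble(puncta_per_cell = c(0, 1, 2, 4, 8),
                          foci_per_cell = c(1, 1.4, 1.5, 2.1, 3.4))
  fit <- fit_mechanism(wells)
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "slope"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_true(all(c("slope", "intercept", "r_squared", "n_points") %in% names(gl)))
})
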