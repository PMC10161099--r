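test_that("pKa fitting recovers a noise-free titration and its midpoint identity", {
  cur <- simulate_titration(pka = 5.7, background = 25, maximum = 900)
  fit <- fit_pka(cur)
  expect_true(fit$converged)
  expect_true(fit$ionizable)
  expect_equal(fit$pka, 5.7, tolerance = 0.01)
  # model value at the fitted pKa is the exact midpoint of the asymptotes
  expect_equal(predict(fit, fit$pka), (fit$background + fit$maximum) / 2,
               tolerance = 1e-9)
})

test_that("flat titration curves are classified non-ionizable", {
  flat <- tibble::tibble(ph = seq(3, 10, 0.5), fluorescence = 500)
  expect_false(glance(fit_pka(flat))$ionizable)
  withr::with_seed(6, {
    noisy <- tibble::tibble(ph = seq(3, 10, 0.5),
                            fluorescence = 500 * (1 + rnorm(15, 0, 0.02)))
  })
  g <- glance(fit_pka(noisy))
  expect_false(g$ionizable)
})

test_that("pKa fitting is scale-equivariant", {
  cur <- simulate_titration(pka = 6.8, background = 15, maximum = 1200,
                            noise_sd = 10, seed = 40)
  f1 <- fit_pka(cur)
  f2 <- fit_pka(dplyr::mutate(cur, fluorescence = fluorescence * 7))
  expect_equal(f2$pka, f1$pka, tolerance = 1e-6)
  expect_equal(f2$background, 7 * f1$background, tolerance = 1e-4)
  expect_equal(f2$maximum, 7 * f1$maximum, tolerance = 1e-4)
})

test_that("pKa parameter recovery stays tight over 100 noisy titrations", {
  errs <- withr::with_seed(42, {
    vapply(1:100, function(i) {
      pka <- runif(1, 4.5, 8.5)
      cur <- simulate_titration(pka, background = 10, maximum = 1000)
      cur$fluorescence <- cur$fluorescence * (1 + rnorm(nrow(cur), 0, 0.02))
      abs(glance(fit_pka(cur))$pka - pka)
    }, numeric(1))
  })
  expect_lt(median(errs), 0.05)
})

test_that("pKa fit input contracts are enforced", {
  expect_error(fit_pka(tibble::tibble(ph = 1:3, fluorescence = 1:3)),
               class = "colloidquant_bad_input")
  expect_error(fit_pka(tibble::tibble(a = 1:5)), class = "colloidquant_bad_input")
})

test_that("viability normalizations reproduce hand arithmetic", {
  # relative: sample = control -> 100%; sample = background -> 0%
  rec <- tibble::tibble(i_sample_6d = c(100, 10, 55),
                        i_background_6d = 10, i_control_6d = 100)
  out <- relative_activity(rec)
  expect_equal(out$relative_activity_pct, c(100, 0, 50))

  # proliferation: day 6 equal to day 0 -> 100%; doubled signal -> 200%
  rec2 <- tibble::tibble(i_sample_6d = c(100, 10, 190),
                         i_background_6d = 10,
                         i_sample_0d = c(100, 50, 100), i_background_0d = 10)
  out2 <- original_activity(rec2)
  expect_equal(out2$original_activity_pct, c(100, 0, 200))

  expect_error(relative_activity(tibble::tibble(
    i_sample_6d = 1, i_background_6d = 5, i_control_6d = 5)),
    class = "colloidquant_bad_input")
  expect_error(original_activity(tibble::tibble(
    i_sample_6d = 1, i_background_6d = 5, i_sample_0d = 5, i_background_0d = 5)),
    class = "colloidquant_bad_input")
})

test_that("noise-free monophasic dose-response data refit to 1%", {
  conc <- 10^seq(-4, 1, 0.25)
  dat <- simulate_dose_response(conc, top = 100, bottom = 0,
                                ic50 = 0.005, hill = 1)
  g <- glance(fit_dose_response(dat))
  expect_true(g$converged)
  expect_equal(g$top, 100, tolerance = 0.01)
  expect_lt(abs(g$bottom), 0.5)  # absolute: true value is 0
  expect_equal(g$ic50, 0.005, tolerance = 0.01)
  expect_equal(g$hill, 1, tolerance = 0.01)
  # low-dose limit of the fitted model is Top
  fit <- fit_dose_response(dat)
  expect_equal(predict(fit, 1e-12), g$top, tolerance = 1e-4)
})

test_that("noise-free biphasic data refit to 1% with ordered transitions", {
  conc <- 10^seq(-5, 2, 0.25)
  dat <- simulate_dose_response(conc, top = 100, plateau = 60, bottom = 0,
                                ic50_stat = 0.005, hill_stat = 1,
                                ic50_tox = 5, hill_tox = 1.5)
  g <- glance(fit_dose_response(dat, "biphasic"))
  expect_true(g$converged)
  expect_equal(g$top, 100, tolerance = 0.01)
  expect_equal(g$plateau, 60, tolerance = 0.01)
  expect_equal(g$ic50_stat, 0.005, tolerance = 0.01)
  expect_equal(g$ic50_tox, 5, tolerance = 0.01)
  expect_equal(g$hill_stat, 1, tolerance = 0.01)
  expect_equal(g$hill_tox, 1.5, tolerance = 0.01)
  expect_lte(g$ic50_stat, g$ic50_tox)
})

test_that("the biphasic model with plateau = top collapses to the monophasic fit", {
  conc <- 10^seq(-4, 2, 0.25)
  # identical data under both generating models when plateau = top
  d_bi <- simulate_dose_response(conc, top = 100, plateau = 100, bottom = 5,
                                 ic50_stat = 0.01, ic50_tox = 2, hill_tox = 1.2)
  d_mono <- simulate_dose_response(conc, top = 100, bottom = 5,
                                   ic50 = 2, hill = 1.2)
  expect_equal(d_bi$activity_percent, d_mono$activity_percent, tolerance = 1e-12)
  g <- glance(fit_dose_response(d_bi))
  expect_equal(g$ic50, 2, tolerance = 0.01)
  expect_equal(g$hill, 1.2, tolerance = 0.01)
})

test_that("fitted monophasic curves are monotone non-increasing in dose", {
  dat <- simulate_dose_response(10^seq(-3, 2, 0.5), top = 95, bottom = 10,
                                ic50 = 0.5, hill = 1.4, noise_sd = 3, seed = 12)
  fit <- fit_dose_response(dat)
  grid <- 10^seq(-4, 3, length.out = 300)
  expect_true(all(diff(predict(fit, grid)) <= 1e-9))
})

test_that("scaling all concentrations by k scales the fitted IC50 by k exactly", {
  dat <- simulate_dose_response(10^seq(-3, 1, 0.5), top = 100, bottom = 0,
                                ic50 = 0.1, hill = 1, noise_sd = 2, seed = 31)
  g1 <- glance(fit_dose_response(dat))
  g2 <- glance(fit_dose_response(
    dplyr::mutate(dat, concentration_uM = concentration_uM * 1000)))
  expect_equal(g2$ic50 / g1$ic50, 1000, tolerance = 1e-6)
  expect_equal(g2$hill, g1$hill, tolerance = 1e-6)
})

test_that("zero-dose rows anchor the fitted top", {
  conc <- c(0, 0, 10^seq(-3, 1, 0.5))
  dat <- simulate_dose_response(conc, top = 90, bottom = 0, ic50 = 0.1)
  g <- glance(fit_dose_response(dat))
  expect_equal(g$top, 90, tolerance = 0.01)
})

test_that("dose-response input contracts are enforced", {
  expect_error(
    fit_dose_response(tibble::tibble(concentration_uM = c(1, 2, 3),
                                     activity_percent = c(1, 2, 3))),
    class = "colloidquant_bad_input")
  expect_error(
    fit_dose_response(tibble::tibble(concentration_uM = -1:5,
                                     activity_percent = 0:6)),
    class = "colloidquant_bad_input")
})
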