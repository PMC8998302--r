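test_that("noiseless logistic data are recovered exactly", {
  d <- simulate_dose_response(ec50 = 10, hill_slope = 1, bottom = 0,
                              noise_cv = 0, seed = 1)
  fit <- fit_curve(d)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 10, tolerance = 0.01)
  expect_equal(fit$hill_slope, 1, tolerance = 0.01)
  expect_equal(fit$bottom, 0, tolerance = 0.5)
  expect_lt(fit$residual_sd, 1e-3)
  td <- tidy(fit)
  expect_identical(td$term, c("top", "bottom", "ec50", "hill_slope"))
  expect_equal(td$estimate[1], 100)
  gl <- glance(fit)
  expect_identical(gl$method, "logistic4")
})

test_that("BMC inversion matches the closed form and is self-consistent", {
  d <- simulate_dose_response(ec50 = 10, hill_slope = 1, bottom = 0,
                              noise_cv = 0, seed = 1)
  fit <- fit_curve(d)
  b25 <- bmc(fit, 0.25)
  expect_false(b25$censored)
  expect_equal(b25$bmc, 10 / 3, tolerance = 0.01)
  # bmc50 equals ec50 when bottom = 0, h = 1 (logistic midpoint identity)
  b50 <- bmc(fit, 0.5)
  expect_equal(b50$bmc, 10, tolerance = 0.01)
  # fitted mean at the uncensored bmc25 is 75% within 1e-6 relative tol
  expect_equal(predict(fit, b25$bmc), 75, tolerance = 1e-6)
  expect_error(bmc(fit, 1.5), "response_fraction")
})

test_that("bmc25 increases strictly with the generating ec50", {
  bmcs <- sapply(c(3, 10, 30, 100), function(e) {
    d <- simulate_dose_response(ec50 = e, noise_cv = 0, seed = 1,
                                concentrations = c(0, 1, 3, 10, 30, 100, 300,
                                                   1000))
    bmc(fit_curve(d))$bmc
  })
  expect_true(all(diff(bmcs) > 0))
})

test_that("censoring: asymptote above benchmark or range too short", {
  # bottom 80% never reaches 75%
  d <- simulate_dose_response(ec50 = 10, bottom = 80, noise_cv = 0, seed = 1)
  expect_true(bmc(fit_curve(d))$censored)
  # flat data at 100%: downstream censored
  d <- simulate_dose_response(ec50 = 1e9, noise_cv = 0, seed = 1)
  expect_true(bmc(fit_curve(d))$censored)
  # tested_max below the analytic bmc25 of the generating curve
  d <- simulate_dose_response(ec50 = 10, noise_cv = 0, seed = 1)
  res <- bmc(fit_curve(d), tested_max = 2) # analytic bmc25 = 10/3 > 2
  expect_true(res$censored)
  expect_true(is.na(res$bmc))
})

test_that("noisy bmc25 recovery stays within 20% for ec50 (seeded)", {
  d <- simulate_dose_response(ec50 = 10, hill_slope = 1, bottom = 0,
                              concentrations = c(0, 1, 3, 10, 30, 100),
                              n_technical = 3, n_biological = 3,
                              noise_cv = 0.10, seed = 2024)
  fit <- fit_curve(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 10) / 10, 0.20)
})

test_that("specificity classification applies the strict Y/X > 3 rule", {
  mk <- function(endpoint, bmc_val, censored = FALSE, tested_max = 1000) {
    tibble::tibble(compound = "cmp", endpoint = endpoint,
                   response_fraction = 0.25,
                   bmc = if (censored) NA_real_ else bmc_val,
                   censored = censored, tested_max = tested_max)
  }
  # ratio 4 -> neurite-specific
  r <- classify_specificity(mk("neurite_area", 50), mk("viability", 200))
  expect_identical(r$label, "neurite_specific")
  expect_equal(r$ratio, 4)
  # ratio exactly 3 -> not neurite-specific (strict inequality)
  r <- classify_specificity(mk("neurite_area", 20), mk("viability", 60))
  expect_identical(r$label, "not_neurite_specific")
  # ratio 2 and ratio 1 -> cytotoxic
  expect_identical(
    classify_specificity(mk("neurite_area", 30), mk("viability", 60))$label,
    "not_neurite_specific")
  expect_identical(
    classify_specificity(mk("neurite_area", 30), mk("viability", 30))$label,
    "not_neurite_specific")
  # censoring: Y censored, X finite -> neurite-specific
  r <- classify_specificity(mk("neurite_area", 30),
                            mk("viability", NA, censored = TRUE))
  expect_identical(r$label, "neurite_specific")
  expect_true(is.na(r$ratio))
  # X censored, Y finite -> not neurite-specific
  expect_identical(
    classify_specificity(mk("neurite_area", NA, censored = TRUE),
                         mk("viability", 30))$label,
    "not_neurite_specific")
  # both censored -> no effect
  expect_identical(
    classify_specificity(mk("neurite_area", NA, censored = TRUE),
                         mk("viability", NA, censored = TRUE))$label,
    "no_effect")
  # swapped endpoints -> error
  expect_error(
    classify_specificity(mk("viability", 30), mk("neurite_area", 60)),
    "swapped|neurite_area")
})

test_that("effect thresholds locate the lowest qualifying concentration", {
  concs <- c(0, 1, 3, 10, 30, 100, 300)
  fits <- list(
    neurite_area = fit_curve(simulate_dose_response(
      endpoint = "neurite_area", ec50 = 10, hill_slope = 1.5,
      concentrations = concs, noise_cv = 0, seed = 1)),
    viability = fit_curve(simulate_dose_response(
      endpoint = "viability", ec50 = 100, hill_slope = 2,
      concentrations = concs, noise_cv = 0, seed = 1))
  )
  thr <- effect_thresholds(fits)
  # analytic: viability < 90 at c > 100*(10/90)^(1/2) = 48.3 -> lowest tested 100
  expect_equal(thr$lowest_cytotoxic_conc, 100)
  # neurite < 75 at c > 10*(1/3)^(1/1.5) = 4.81 -> lowest tested 10
  expect_equal(thr$lowest_neurite_effect_conc, 10)
  expect_true(thr$lowest_cytotoxic_conc %in% concs)

  # flat viability -> no cytotoxic concentration
  fits$viability <- fit_curve(simulate_dose_response(
    endpoint = "viability", ec50 = 1e9, concentrations = concs,
    noise_cv = 0, seed = 1))
  expect_true(is.na(effect_thresholds(fits)$lowest_cytotoxic_conc))
  expect_error(effect_thresholds(fits, concentrations = numeric(0)), "Empty")
})

test_that("fit_curve enforces its input contract", {
  d <- simulate_dose_response(noise_cv = 0, seed = 1)
  expect_error(fit_curve(dplyr::filter(d, concentration_nM > 0)),
               "Control records")
  expect_error(fit_curve(dplyr::filter(d, concentration_nM %in% c(0, 1, 3))),
               "3 distinct nonzero")
  expect_warning(fit_curve(dplyr::filter(d,
                                         concentration_nM %in% c(0, 1, 3, 10))),
                 "Fewer than 4")
  d$value_pct_control[1] <- NA
  expect_error(fit_curve(d), "finite")
})
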