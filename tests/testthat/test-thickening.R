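test_that("fit_power_law inverts noiseless model-generated data", {
  params <- list(c(a = 10, b = 0.05), c(a = 6.493, b = 0.0465),
                 c(a = 11.73, b = 0.0496))
  for (p in params) {
    t <- c(1, 3, 10, 30, 100)
    fit <- fit_power_law(thickening_curve(t, p["a"] * t^p["b"]))
    expect_equal(fit$a, unname(p["a"]), tolerance = 1e-6)
    expect_equal(fit$b, unname(p["b"]), tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  # rounded published-style points still invert to 1e-4
  fit <- fit_power_law(thickening_curve(c(1, 10, 100), c(10.0, 11.2202, 12.5893)))
  expect_equal(fit$a, 10.0, tolerance = 1e-4)
  expect_equal(fit$b, 0.05, tolerance = 1e-3)
})

test_that("a flat series fits b = 0 with a warning (no silent clamping)", {
  tc <- thickening_curve(c(1, 10, 100), c(5, 5, 5))
  expect_warning(fit <- fit_power_law(tc), class = "parameter_range_warning")
  expect_equal(fit$b, 0, tolerance = 1e-9)
  expect_equal(fit$a, 5.0, tolerance = 1e-12)
})

test_that("fit_power_law recovers parameters under seeded multiplicative noise", {
  tc <- gen_thickening_curve(a = 11.73, b = 0.0496, n_points = 30,
                             time_range = c(1, 90), noise_level = 0.01,
                             seed = 42)
  fit <- fit_power_law(tc)
  expect_lt(abs(fit$a - 11.73) / 11.73, 0.02)
  expect_lt(abs(fit$b - 0.0496) / 0.0496, 0.10)
  # nonlinear refinement stays close to the log-log solution on clean data
  fit2 <- fit_power_law(tc, refine = TRUE)
  expect_equal(fit2$a, fit$a, tolerance = 0.01)
  expect_identical(fit2$scale, "nonlinear")
})

test_that("fit_power_law rejects unusable inputs", {
  expect_sf_error(fit_power_law(thickening_curve(c(0, 5), c(6, 7))),
                  "insufficient_data_error")
  # points at t = 0 are excluded from the fit
  tc <- thickening_curve(c(0, 1, 10, 100), c(6, 10, 11.22, 12.59))
  expect_equal(fit_power_law(tc)$n_points, 3L)
  expect_sf_error(thickening_curve(c(1, 2, 3), c(5, -1, 6)), "validation_error")
  expect_sf_error(thickening_curve(c(1, 3, 2), c(5, 5, 5)), "validation_error")
})

test_that("predict_bottom_concentration matches direct evaluation and clamps at X0", {
  fit <- list(a = 11.73, b = 0.0496)
  expect_equal(as.numeric(predict_bottom_concentration(fit, 1)), 11.73)
  expect_equal(as.numeric(predict_bottom_concentration(fit, 90)),
               11.73 * 90^0.0496, tolerance = 1e-12)
  expect_equal(as.numeric(predict_bottom_concentration(fit, 90)), 14.66,
               tolerance = 0.01)
  clamped <- predict_bottom_concentration(list(a = 6.493, b = 0.0465), 1,
                                          X0 = 6.600)
  expect_equal(as.numeric(clamped), 6.600)
  expect_true(attr(clamped, "clamped"))
  free <- predict_bottom_concentration(list(a = 6.493, b = 0.0465), 90,
                                       X0 = 6.600)
  expect_false(attr(free, "clamped"))
  expect_sf_error(predict_bottom_concentration(fit, 0.5), "domain_error")
})

test_that("sludge_height obeys the blanket mass balance exactly", {
  fit <- list(a = 6.493, b = 0.0465)
  x0 <- 1; X0 <- 6.600
  expect_equal(sludge_height(fit, x0, X0, 90), 6.6 / (6.493 * 90^0.0465),
               tolerance = 1e-12)
  expect_equal(sludge_height(fit, x0, X0, 90), 0.8246, tolerance = 1e-3)
  # at the time where X_d = X0 the blanket is still at x0 (clamped identity)
  t0 <- (X0 / fit$a)^(1 / fit$b)
  expect_equal(sludge_height(fit, x0, X0, t0), x0, tolerance = 1e-12)
  # linear in x0
  ts <- c(1, 5, 30, 90)
  expect_equal(sludge_height(fit, 2 * x0, X0, ts),
               2 * sludge_height(fit, x0, X0, ts), tolerance = 1e-14)
})

test_that("mass conservation and monotonicity hold across random parameter draws", {
  set.seed(101)
  for (i in 1:25) {
    a <- runif(1, 5, 15); b <- runif(1, 0.02, 0.3)
    x0 <- runif(1, 0.4, 2); X0 <- runif(1, 2, a)
    fit <- list(a = a, b = b)
    ts <- sort(runif(12, 1, 120))
    xd <- as.numeric(predict_bottom_concentration(fit, ts, X0 = X0))
    x <- sludge_height(fit, x0, X0, ts)
    expect_equal(x * xd, rep(x0 * X0, 12), tolerance = 1e-12)
    expect_true(all(diff(xd) >= 0))
    expect_true(all(diff(x) <= 0))
    expect_true(all(x <= x0 * (1 + 1e-12)))
  }
})

test_that("sensitivity closed form b*ln(t) matches numeric differentiation", {
  b <- 0.0465
  for (ts in c(1, 10, 60, 90)) {
    S_num <- num_deriv(function(bb) 6.493 * ts^bb, b) * b / (6.493 * ts^b)
    expect_equal(sensitivity_to_b(b, ts), S_num, tolerance = 1e-6)
  }
  expect_equal(sensitivity_to_b(b, 1), 0)
  expect_equal(sensitivity_to_b(b, 60), 0.1904, tolerance = 1e-3)
  expect_lt(sensitivity_to_b(b, 60), 0.2)
  expect_equal(sensitivity_to_b(b, 90), 0.2092, tolerance = 1e-3)
})

test_that("return_concentration is k*X_d with validated k", {
  expect_equal(return_concentration(6.600, return_sludge_spec("scrape")), 4.620)
  expect_equal(return_concentration(8.050, 0.7), 5.635)
  expect_equal(return_concentration(7.3, 1), 7.3)
  # linear and monotone in both arguments
  xd <- c(5, 6, 7)
  expect_equal(return_concentration(2 * xd, 0.6), 2 * return_concentration(xd, 0.6))
  expect_true(all(diff(return_concentration(xd, 0.6)) > 0))
  expect_lt(return_concentration(5, 0.5), return_concentration(5, 0.7))
  expect_sf_error(return_concentration(5, 1.2), "validation_error")
  expect_sf_error(return_concentration(5, 0), "validation_error")
  expect_sf_error(return_sludge_spec("suction", k = 0.4), "validation_error")
  expect_sf_error(return_sludge_spec("scrape", k = 0.6), "validation_error")
  expect_equal(return_sludge_spec("suction", k = 0.55)$k, 0.55)
})
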