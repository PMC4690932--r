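test_that("extract_hindered_velocity reads an exact line and noisy two-phase curves", {
  t <- seq(0, 20, by = 1)
  curve <- batch_settling_curve(t, 1 - 0.02 * t, X0 = 3, x0 = 1)
  v <- extract_hindered_velocity(curve)
  expect_equal(as.numeric(v), 1.2, tolerance = 1e-9)
  # seeded two-phase curve: generator truth 0.6 m/h, +-5%
  noisy <- gen_batch_settling_curve(v = 0.6, t_star = 20, noise_level = 0.005,
                                    seed = 11)
  expect_lt(abs(as.numeric(extract_hindered_velocity(noisy)) - 0.6) / 0.6, 0.05)
})

test_that("a sharply convex curve has no hindered zone", {
  t <- 0:14
  h <- 0.02 + 0.98 * (1 + t)^-2.5
  curve <- batch_settling_curve(t, h, X0 = 3, x0 = 1)
  expect_sf_error(extract_hindered_velocity(curve), "no_linear_zone_error")
})

test_that("fit_vesilind inverts noiseless data generated from known constants", {
  X <- c(2.010, 3.025, 4.100, 5.180, 6.425)
  fit <- fit_vesilind(X, 11.043 * exp(-0.364 * X))
  expect_equal(fit$v0, 11.043, tolerance = 1e-6)
  expect_equal(fit$n, 0.364, tolerance = 1e-6)
  expect_equal(predict_vesilind(fit, 0), fit$v0)
  expect_equal(predict_vesilind(fit, 6.6), 1.000, tolerance = 5e-3)
  expect_sf_error(fit_vesilind(c(2, 2, 2), c(1, 1, 1)), "validation_error")
  expect_sf_error(fit_vesilind(c(2, 3, 4), c(1, -1, 1)), "validation_error")
})

test_that("compression velocity: unit base, printed exponent, strict decrease", {
  law <- compression_law(a = 6.493, b = 0.0465, x0 = 1, X0 = 6.600)
  # at X = a the power term is 1: v = b*x0*X0/a (an extrapolation, a < X0)
  v_base <- compression_velocity(law, 6.493, check_domain = FALSE)
  expect_equal(v_base / 60, 0.0465 * 1 * 6.6 / 6.493, tolerance = 1e-12)
  expect_equal(v_base / 60, 0.04727, tolerance = 1e-3)
  expect_equal(v_base, 2.836, tolerance = 0.06)
  expect_equal((1 + 0.0465) / 0.0465, 22.5, tolerance = 0.01)
  X <- seq(6.6, 14, length.out = 50)
  expect_true(all(diff(compression_velocity(law, X)) < 0))
  expect_sf_error(compression_velocity(law, 6.0), "domain_error")
})

test_that("time form and concentration form of the compression law agree", {
  law <- compression_law(6.493, 0.0465, 1, 6.6)
  expect_equal(compression_velocity_at_time(law, 1) / 60,
               0.0465 * 6.6 / 6.493, tolerance = 1e-14)
  expect_lt(abs(compression_velocity_at_time(law, 90) - 0.0255), 1e-3)
  expect_sf_error(compression_velocity_at_time(law, 0.5), "domain_error")
  # Eq-5/Eq-6 style identity over random draws: composing the time form with
  # the thickening law equals the concentration form; and both match the
  # centered-difference derivative of the blanket height
  set.seed(202)
  for (i in 1:20) {
    a <- runif(1, 5, 12); b <- runif(1, 0.03, 0.12)
    x0 <- runif(1, 0.5, 1.5); X0 <- runif(1, 2, a * 0.98)
    lw <- compression_law(a, b, x0, X0)
    ts <- sort(runif(8, 1.5, 120))
    Xd <- a * ts^b
    expect_equal(compression_velocity_at_time(lw, ts),
                 compression_velocity(lw, Xd, check_domain = FALSE),
                 tolerance = 1e-12)
    fitl <- list(a = a, b = b)
    v_num <- -vapply(ts, function(t0)
      num_deriv(function(tt) sludge_height(fitl, x0, X0, tt), t0), numeric(1))
    expect_equal(compression_velocity_at_time(lw, ts) / 60, v_num,
                 tolerance = 1e-6)
  }
})

make_integrated <- function(X_c = 8.25) {
  X <- c(2.010, 3.025, 4.100, 5.180, 6.425)
  integrated_settling_model(
    fit_vesilind(X, 11.043 * exp(-0.364 * X)),
    compression_law(6.493, 0.0465, 1, 6.600),
    X_c = X_c)
}

test_that("integrated model selects branches and drops at the onset", {
  m <- make_integrated()
  v_lo <- integrated_velocity(m, m$X_c / 2)
  expect_identical(attr(v_lo, "branch"), "hindered")
  expect_equal(as.numeric(v_lo), predict_vesilind(m$vesilind, m$X_c / 2))
  v_hi <- integrated_velocity(m, m$X_c * 1.001)
  expect_identical(attr(v_hi, "branch"), "compression")
  # compression settling is slower than hindered settling at the handover
  expect_lt(as.numeric(v_hi), predict_vesilind(m$vesilind, m$X_c))
  expect_gt(continuity_gap(m), 0)
  # full profile: finite, positive, branchwise monotone decreasing
  X <- seq(1, 14, by = 0.1)
  v <- as.numeric(integrated_velocity(m, X))
  expect_true(all(is.finite(v) & v > 0))
  br <- attr(integrated_velocity(m, X), "branch")
  expect_true(all(diff(v[br == "hindered"]) < 0))
  vc <- v[br == "compression" & X > m$compression$X0]
  expect_true(all(diff(vc) < 0))
})

test_that("flux curve: limits, gravity reduction, and hindered/integrated ordering", {
  m <- make_integrated()
  fc0 <- flux_curve(m, u = 0, X_grid = c(1e-6, 1, 3))
  expect_lt(fc0$flux[1], 1e-4)                      # flux -> 0 as X -> 0
  expect_equal(fc0$flux, as.numeric(integrated_velocity(m, fc0$X)) * fc0$X)
  # hindered-only gravity flux dominates above the onset
  Xg <- seq(m$X_c + 0.01, 14, length.out = 100)
  fc <- flux_curve(m, u = 0, X_grid = Xg)
  expect_true(all(fc$flux_hindered >= fc$flux))
  expect_sf_error(flux_curve(m, 0, numeric(0)), "validation_error")
  expect_sf_error(flux_curve(m, -1, c(1, 2)), "validation_error")
})

test_that("limiting flux: Vesilind calculus identity and variant ordering", {
  m <- make_integrated()
  # closed form: gravity flux v0*X*exp(-nX) peaks at X = 1/n
  vf <- m$vesilind
  opt <- stats::optimize(function(X) predict_vesilind(vf, X) * X,
                         c(0.1, 10), maximum = TRUE)
  expect_equal(opt$maximum, 1 / vf$n, tolerance = 1e-4)
  lim <- suppressWarnings(limiting_flux(m, u = 0.3))
  expect_lte(lim$integrated$flux, lim$hindered$flux)
  expect_gte(lim$overestimate, 0)
  # hindered-only variant has an interior minimum away from the bounds
  expect_gt(lim$hindered$X, m$X_c)
})
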