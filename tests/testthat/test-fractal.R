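test_that("analytic disks give (D2, D3, DB) = (2, 3, 1) exactly", {
  r <- c(2, 4, 8, 16, 32)
  m <- data.frame(area = pi * r^2, perimeter = 2 * pi * r,
                  volume = 4 / 3 * pi * r^3)
  est <- fit_fractal_dimensions(m)
  expect_equal(est$D2, 2.0, tolerance = 0.02)
  expect_equal(est$D3, 3.0, tolerance = 0.02)
  expect_equal(est$DB, 1.0, tolerance = 0.02)
})

test_that("a constructed power law A = c*P^1.2 is recovered to machine precision", {
  P <- exp(seq(log(10), log(1000), length.out = 12))
  m <- data.frame(area = 0.4 * P^1.2, perimeter = P, volume = 0.1 * P^1.8)
  est <- suppressWarnings(fit_fractal_dimensions(m))
  expect_equal(est$D2, 1.2, tolerance = 1e-9)
  expect_equal(est$D3, 1.8, tolerance = 1e-9)
  expect_equal(est$DB, 2 / 1.2, tolerance = 1e-9)
})

test_that("fractal estimates are scale invariant", {
  r <- c(3, 6, 12, 24, 48)
  m <- data.frame(area = pi * r^2 * 1.1, perimeter = 2 * pi * r * 1.2,
                  volume = 4 / 3 * pi * r^3)
  e1 <- fit_fractal_dimensions(m)
  s <- 37.3
  m2 <- data.frame(area = m$area * s^2, perimeter = m$perimeter * s,
                   volume = m$volume * s^3)
  e2 <- fit_fractal_dimensions(m2)
  expect_equal(e1$D2, e2$D2, tolerance = 1e-9)
  expect_equal(e1$D3, e2$D3, tolerance = 1e-9)
  expect_equal(e1$DB, e2$DB, tolerance = 1e-9)
})

test_that("spread diagnostics: single-decade warning and degenerate errors", {
  P <- seq(10, 30, length.out = 6)
  m <- data.frame(area = 0.05 * P^2, perimeter = P, volume = 0.01 * P^3)
  expect_warning(fit_fractal_dimensions(m), class = "single_decade_warning")
  m$perimeter <- rep(10, 6)
  m$area <- rep(5, 6); m$volume <- rep(50, 6)
  expect_sf_error(fit_fractal_dimensions(m), "insufficient_spread_error")
  expect_sf_error(fit_fractal_dimensions(m[1:3, ]), "insufficient_data_error")
})

test_that("measure_flocs meets analytic expectations on a rasterized disk", {
  img <- disk_image(20)
  m <- measure_flocs(img)
  expect_equal(nrow(m), 1L)
  expect_lt(abs(m$area - pi * 400) / (pi * 400), 0.02)
  expect_lt(abs(m$perimeter - 2 * pi * 20) / (2 * pi * 20), 0.03)
  expect_equal(m$volume, 4 / 3 * pi * (sqrt(m$area / pi))^3, tolerance = 1e-9)
  # a 2-px speck is removed by the area filter
  img2 <- img
  img2[3:4, 50] <- 255
  expect_equal(nrow(measure_flocs(img2, min_area = 10)), 1L)
  expect_sf_error(measure_flocs(img, min_area = 2), "validation_error")
})

test_that("border-touching blobs are excluded from the count", {
  set <- gen_floc_image_set(n_flocs = 13, n_border = 2, roughness = 0.05,
                            radius_range = c(6, 16), seed = 9)
  expect_equal(nrow(set$truth), 15L)
  m <- measure_flocs(set$image)
  expect_equal(nrow(m), 13L)
})

test_that("rasterized disks from the generator recover smooth-shape dimensions", {
  set <- gen_floc_image_set(n_flocs = 10, roughness = 0, seed = 5,
                            radius_range = c(6, 25))
  est <- suppressWarnings(fit_fractal_dimensions(measure_flocs(set$image)))
  expect_equal(est$D2, 2.0, tolerance = 0.05)
  expect_equal(est$D3, 3.0, tolerance = 0.08)
  expect_equal(est$DB, 1.0, tolerance = 0.05)
})

test_that("boundary roughness increases the measured boundary dimension", {
  db_at <- function(rough) {
    ms <- do.call(rbind, lapply(1:3, function(s) {
      set <- gen_floc_image_set(12, radius_range = c(4, 22), roughness = rough,
                                img_size = c(220L, 220L),
                                seed = s * 100 + round(rough * 1000))
      measure_flocs(set$image)
    }))
    suppressWarnings(fit_fractal_dimensions(ms))$DB
  }
  levels <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3)
  dbs <- vapply(levels, db_at, numeric(1))
  expect_gt(dbs[6], dbs[1])
  expect_gt(stats::cor(levels, dbs, method = "spearman"), 0.9)
})

test_that("otsu separates a bimodal image and empty results only warn", {
  img <- matrix(10, 40, 40)
  img[10:20, 10:20] <- 240
  th <- otsu_threshold(img)
  expect_gt(th, 10); expect_lt(th, 240)
  blank <- matrix(0, 30, 30)
  expect_warning(m <- measure_flocs(blank + c(0, 1)), # near-constant noise image
                 class = "empty_result_warning")
  expect_equal(nrow(m), 0L)
})

test_that("svi_fractal_trend reports the expected signs", {
  set.seed(7)
  svi <- c(60, 90, 130, 180, 230)
  panel <- data.frame(
    svi = svi,
    D2 = (1.9 - 0.003 * svi) * (1 + rnorm(5, 0, 0.01)),
    D3 = (2.8 - 0.004 * svi) * (1 + rnorm(5, 0, 0.01)),
    DB = (1.1 + 0.002 * svi) * (1 + rnorm(5, 0, 0.01)))
  tr <- svi_fractal_trend(panel)
  expect_equal(tr$sign[tr$dimension == "D2"], -1)
  expect_equal(tr$sign[tr$dimension == "D3"], -1)
  expect_equal(tr$sign[tr$dimension == "DB"], 1)
  # constant dimensions: zero slopes
  const <- data.frame(svi = svi, D2 = 1.5, D3 = 2.2, DB = 1.3)
  expect_true(all(abs(svi_fractal_trend(const)$slope) < 1e-9))
  expect_sf_error(svi_fractal_trend(panel[1:2, ]), "insufficient_data_error")
})
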