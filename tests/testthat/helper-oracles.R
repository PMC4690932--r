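# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: closed-form OLS from raw sums, centered finite
# differences, an equidistance formulation of the angle bisector, and
# directly rasterized disks.

# closed-form simple OLS (sums, no lm)
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# centered finite difference
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# Onset oracle: the interior angle bisector of two lines is the locus of
# equal perpendicular distance. On a dense interpolation of the normalized
# curve, find where distance-to-hindered-tangent equals
# distance-to-compression-tangent (beyond the hindered zone).
onset_oracle_tc <- function(curve, est, n_dense = 20000L) {
  d <- est$diagnostics
  t_max <- max(curve$times)
  m1 <- d$hindered$slope_m_min * t_max / curve$x0
  c1 <- d$hindered$intercept_m / curve$x0
  m2 <- d$compression$slope_m_min * t_max / curve$x0
  c2 <- d$compression$intercept_m / curve$x0
  Tn <- seq(0, 1, length.out = n_dense)
  Hn <- stats::approx(curve$times / t_max, curve$heights / curve$x0,
                      xout = Tn)$y
  d1 <- abs(m1 * Tn - Hn + c1) / sqrt(1 + m1^2)
  d2 <- abs(m2 * Tn - Hn + c2) / sqrt(1 + m2^2)
  t_v <- (c2 - c1) / (m1 - m2)   # vertex abscissa (normalized)
  diff_d <- d1 - d2
  past <- which(Tn > t_v)
  cross <- past[which(diff(sign(diff_d[past])) != 0)[1]]
  Tn[cross] * t_max
}

# binary disk raster
disk_image <- function(r, pad = 10L, value = 255) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- pad + r + 1L
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  img <- matrix(0, n, n)
  img[(yy - ctr)^2 + (xx - ctr)^2 <= r^2] <- value
  img
}

expect_sf_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
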