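# Settling-velocity model family: hindered (Vesilind) settling calibrated
# from batch tests, a compression settling law derived from the thickening
# mass balance, and the integrated piecewise velocity model used for
# solids-flux analysis. All public velocities are m/h; the compression law
# works internally in m/min (column heights in m, thickening time in min)
# and is converted at the interface.

#' Construct a batch settling curve
#'
#' Interface height of the sludge blanket versus time in a batch settling
#' test column.
#'
#' @param times Minutes, strictly increasing.
#' @param heights Interface heights in m, positive, `<= x0`, non-increasing
#'   up to a noise tolerance.
#' @param X0 Initial sludge concentration in g/L.
#' @param x0 Initial blanket height in m.
#' @param noise_tol Permitted upward excursion between consecutive heights as
#'   a fraction of `x0` (instrument noise); default 2%.
#' @return An object of class `batch_settling_curve`.
#' @export
batch_settling_curve <- function(times, heights, X0, x0, noise_tol = 0.02) {
  check_numeric_vec(times, "times")
  check_numeric_vec(heights, "heights", positive = TRUE)
  check_number(X0, "X0", positive = TRUE)
  check_number(x0, "x0", positive = TRUE)
  if (length(times) != length(heights))
    sf_error("validation_error", "`times` and `heights` differ in length")
  check_strictly_increasing(times, "times")
  if (any(heights > x0 * (1 + noise_tol)))
    sf_error("validation_error", "heights exceed the initial height x0")
  ups <- which(diff(heights) > noise_tol * x0)
  if (length(ups))
    sf_error("validation_error",
             sprintf("heights increase beyond noise tolerance at row %d", ups[1] + 1L))
  structure(list(times = as.numeric(times), heights = as.numeric(heights),
                 X0 = X0, x0 = x0),
            class = "batch_settling_curve")
}

#' @export
print.batch_settling_curve <- function(x, ...) {
  cat(sprintf("Batch settling curve: n = %d, t = %g-%g min, X0 = %g g/L, x0 = %g m\n",
              length(x$times), min(x$times), max(x$times), x$X0, x$x0))
  invisible(x)
}

# linear fit over a window of a curve; returns slope/intercept/R^2.
# R^2 is computed by hand so a perfectly flat window counts as a perfect fit
# (lm's R^2 is 0/0 there).
window_linfit <- function(t, h) {
  fit <- stats::lm(h ~ t)
  res <- stats::resid(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((h - mean(h))^2)
  r2 <- if (ss_tot < 1e-24) {
    if (ss_res < 1e-24) 1 else 0
  } else 1 - ss_res / ss_tot
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]), r_squared = r2)
}

# Search for the hindered-zone tangent. The hindered zone starts at the
# beginning of the record (possibly after a short lag), so the window is
# anchored at the earliest start index (within the first third) whose
# minimal window passes the linearity threshold, then grown forward while
# R^2 stays above the threshold; among the grown prefixes the longest one
# whose R^2 is within `tie_tol` of the best is kept. Growing-by-length
# alone would absorb the gently sloped compression tail, which on long
# records can masquerade as the "longest linear segment".
find_hindered_window <- function(curve, min_window = 4L, r2_min = 0.95,
                                 tie_tol = 1e-3) {
  t <- curve$times; h <- curve$heights
  n <- length(t)
  max_start <- max(1L, ceiling(n / 3))
  for (i in seq_len(max_start)) {
    j0 <- i + min_window - 1L
    if (j0 > n) break
    fits <- list()
    for (j in j0:n) {
      fj <- window_linfit(t[i:j], h[i:j])
      if (fj$r_squared < r2_min) break
      fits[[length(fits) + 1L]] <- fj
    }
    if (!length(fits)) next
    r2s <- vapply(fits, `[[`, numeric(1), "r_squared")
    k <- max(which(r2s >= max(r2s) - tie_tol))
    return(c(fits[[k]], list(from = i, to = j0 + k - 1L, len = j0 + k - i)))
  }
  NULL
}

#' Hindered settling velocity from a batch curve
#'
#' The hindered (zone) settling velocity is the slope of the straight early
#' portion of the interface-height curve. The straight segment is found by a
#' window search: the longest window of at least `min_window` points that
#' starts within the first third of the record and achieves `R^2 >= r2_min`.
#'
#' @param curve A [batch_settling_curve()] with at least 6 points.
#' @param min_window Minimum window length (points), default 4.
#' @param r2_min Linearity acceptance threshold, default 0.95.
#' @return Hindered velocity in m/h (positive), with attributes `window`
#'   (index range used), `r_squared`, `slope_m_min` and `intercept_m`.
#' @export
extract_hindered_velocity <- function(curve, min_window = 4L, r2_min = 0.95) {
  if (!inherits(curve, "batch_settling_curve"))
    sf_error("validation_error", "`curve` must be a batch_settling_curve")
  if (length(curve$times) < 6L)
    sf_error("insufficient_data_error", "need at least 6 points")
  best <- find_hindered_window(curve, min_window, r2_min)
  if (is.null(best))
    sf_error("no_linear_zone_error",
             sprintf("no early window of >= %d points reaches R^2 >= %g",
                     min_window, r2_min))
  v <- -best$slope * 60
  structure(v, window = c(best$from, best$to), r_squared = best$r_squared,
            slope_m_min = best$slope, intercept_m = best$intercept)
}

#' Fit the Vesilind hindered-settling law
#'
#' `v = v0 * exp(-n X)`: least squares of `ln(v)` on the initial
#' concentration `X0` of each batch test.
#'
#' @param X Initial concentrations in g/L (>= 3 distinct values).
#' @param v Hindered settling velocities in m/h, `> 0`.
#' @return A `vesilind_fit` with `v0` (m/h), `n` (L/g), `r_squared`.
#' @export
#' @examples
#' X <- c(2.010, 3.025, 4.100, 5.180, 6.425)
#' fit_vesilind(X, 11.043 * exp(-0.364 * X))
fit_vesilind <- function(X, v) {
  check_numeric_vec(X, "X", positive = TRUE)
  check_numeric_vec(v, "v", positive = TRUE)
  if (length(X) != length(v))
    sf_error("validation_error", "`X` and `v` differ in length")
  if (length(unique(X)) < 3L)
    sf_error("validation_error", "need at least 3 distinct concentrations")
  fit <- stats::lm(log(v) ~ X)
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  if (is.nan(r2)) r2 <- 1
  structure(list(v0 = exp(unname(stats::coef(fit)[1])),
                 n = -unname(stats::coef(fit)[2]),
                 r_squared = r2, n_points = length(X)),
            class = "vesilind_fit")
}

#' Evaluate a Vesilind fit
#' @param fit A `vesilind_fit`.
#' @param X Concentration(s) in g/L.
#' @return Hindered settling velocity in m/h.
#' @export
predict_vesilind <- function(fit, X) {
  if (!inherits(fit, "vesilind_fit"))
    sf_error("validation_error", "`fit` must be a vesilind_fit")
  check_numeric_vec(X, "X")
  fit$v0 * exp(-fit$n * X)
}

#' @export
print.vesilind_fit <- function(x, ...) {
  cat(sprintf("Vesilind fit: v = %.4g * exp(-%.4g X) m/h (R^2 = %.4g, n = %d)\n",
              x$v0, x$n, x$r_squared, x$n_points))
  invisible(x)
}

#' Compression settling law
#'
#' The thickening power law plus the blanket mass balance
#' `x * X_d = x0 * X0` imply the compression settling velocity
#' `v_cs = -dx/dt_s = (b x0 X0 / a) t_s^(-1-b)` in time form, or
#' `v_cs = (b x0 X0 / a) (X/a)^(-(1+b)/b)` in concentration form. At the
#' fleet-mean exponent b = 0.0465 the concentration exponent
#' `(1+b)/b` is 22.5: compression velocity collapses steeply as the blanket
#' concentrates.
#'
#' @param a Thickening coefficient in g/L (`> 0`).
#' @param b Thickening exponent, in (0, 1).
#' @param x0 Initial blanket height in m.
#' @param X0 Initial concentration in g/L.
#' @return An object of class `compression_law`.
#' @export
compression_law <- function(a, b, x0, X0) {
  check_number(a, "a", positive = TRUE)
  check_number(b, "b", positive = TRUE)
  check_number(x0, "x0", positive = TRUE)
  check_number(X0, "X0", positive = TRUE)
  if (b >= 1)
    sf_error("validation_error", "b must be < 1 for a thickening law")
  structure(list(a = a, b = b, x0 = x0, X0 = X0), class = "compression_law")
}

#' Build a compression law from a thickening fit
#' @param fit A `power_law_fit`.
#' @inheritParams compression_law
#' @export
compression_law_from_fit <- function(fit, x0, X0) {
  fit <- resolve_fit(fit)
  compression_law(fit$a, fit$b, x0, X0)
}

#' @export
print.compression_law <- function(x, ...) {
  cat(sprintf("Compression law: v_cs = %.4g * (X/%.4g)^-%.4g m/min (x0 = %g m, X0 = %g g/L)\n",
              x$b * x$x0 * x$X0 / x$a, x$a, (1 + x$b) / x$b, x$x0, x$X0))
  invisible(x)
}

#' Compression settling velocity at a concentration
#'
#' @param law A [compression_law()].
#' @param X Concentration(s) in g/L, `>= law$X0` (the law only applies inside
#'   the compression zone).
#' @param check_domain If `TRUE` (default), concentrations below `X0` raise a
#'   domain error. Set `FALSE` to evaluate the bare power law outside the
#'   compression zone (e.g. at its unit base `X = a`, which can sit slightly
#'   below `X0`); such values are extrapolations.
#' @return Velocity in m/h, strictly decreasing in `X`.
#' @export
compression_velocity <- function(law, X, check_domain = TRUE) {
  if (!inherits(law, "compression_law"))
    sf_error("validation_error", "`law` must be a compression_law")
  check_numeric_vec(X, "X")
  if (check_domain && any(X < law$X0))
    sf_error("domain_error",
             sprintf("X must be >= X0 = %g g/L (compression zone only)", law$X0))
  v_m_min <- (law$b * law$x0 * law$X0 / law$a) * (X / law$a)^(-(1 + law$b) / law$b)
  v_m_min * 60
}

#' Compression settling velocity at a thickening time
#'
#' Time form of the law: `v_cs = (b x0 X0 / a) t_s^(-1-b)`. Algebraically
#' identical to [compression_velocity()] evaluated at `X = a t_s^b`.
#'
#' @param law A [compression_law()].
#' @param t_s Thickening time(s) in minutes, `>= 1`.
#' @return Velocity in m/h.
#' @export
compression_velocity_at_time <- function(law, t_s) {
  if (!inherits(law, "compression_law"))
    sf_error("validation_error", "`law` must be a compression_law")
  check_numeric_vec(t_s, "t_s")
  if (any(t_s < 1))
    sf_error("domain_error", "t_s must be >= 1 min")
  (law$b * law$x0 * law$X0 / law$a) * t_s^(-1 - law$b) * 60
}

#' Integrated hindered + compression settling model
#'
#' Piecewise settling velocity: the Vesilind law below the compression-onset
#' concentration `X_c`, the compression law above it. No continuity
#' condition is imposed at `X_c`; the branch disagreement there is an honest
#' property of the model and is reported by [continuity_gap()].
#'
#' @param vesilind A `vesilind_fit`.
#' @param compression A `compression_law`.
#' @param X_c Compression-onset concentration in g/L, `> 0`.
#' @return An object of class `integrated_settling_model`.
#' @export
integrated_settling_model <- function(vesilind, compression, X_c) {
  if (!inherits(vesilind, "vesilind_fit"))
    sf_error("validation_error", "`vesilind` must be a vesilind_fit")
  if (!inherits(compression, "compression_law"))
    sf_error("validation_error", "`compression` must be a compression_law")
  check_number(X_c, "X_c", positive = TRUE)
  structure(list(vesilind = vesilind, compression = compression, X_c = X_c),
            class = "integrated_settling_model")
}

#' Velocity branch disagreement at the onset concentration
#' @param model An [integrated_settling_model()].
#' @return Hindered minus compression velocity at `X_c`, m/h.
#' @export
continuity_gap <- function(model) {
  predict_vesilind(model$vesilind, model$X_c) -
    compression_velocity(model$compression, max(model$X_c, model$compression$X0))
}

#' Evaluate the integrated settling velocity
#'
#' @param model An [integrated_settling_model()].
#' @param X Concentration(s) in g/L, `> 0`.
#' @return Velocity in m/h, with a character attribute `"branch"` recording
#'   `"hindered"` or `"compression"` per element. Concentrations above `X_c`
#'   but below the compression law's `X0` are evaluated at `X0` (the law's
#'   lower edge) to keep the profile defined.
#' @export
integrated_velocity <- function(model, X) {
  if (!inherits(model, "integrated_settling_model"))
    sf_error("validation_error", "`model` must be an integrated_settling_model")
  check_numeric_vec(X, "X", positive = TRUE)
  v <- numeric(length(X))
  comp <- X > model$X_c
  branch <- ifelse(comp, "compression", "hindered")
  if (any(!comp)) v[!comp] <- predict_vesilind(model$vesilind, X[!comp])
  if (any(comp)) {
    Xeff <- pmax(X[comp], model$compression$X0)
    v[comp] <- compression_velocity(model$compression, Xeff)
  }
  attr(v, "branch") <- branch
  v
}

#' Solids-flux curve
#'
#' Total solids flux through a settler cross-section, `G(X) = (v(X) + u) X`,
#' in kg/(m^2 h) (g/L times m/h is numerically kg/(m^2 h)). Computed for the
#' integrated model and for the hindered-only (Vesilind everywhere) variant,
#' whose comparison quantifies how much a hindered-only flux analysis
#' overestimates permissible loading.
#'
#' @param model An [integrated_settling_model()].
#' @param u Underflow (withdrawal) velocity in m/h, `>= 0`.
#' @param X_grid Concentrations in g/L, `> 0`, non-empty.
#' @return A data.frame with columns `X`, `flux` (integrated model) and
#'   `flux_hindered` (Vesilind-only).
#' @export
flux_curve <- function(model, u, X_grid) {
  if (!inherits(model, "integrated_settling_model"))
    sf_error("validation_error", "`model` must be an integrated_settling_model")
  check_number(u, "u")
  if (u < 0) sf_error("validation_error", "u must be >= 0")
  if (length(X_grid) == 0L)
    sf_error("validation_error", "empty concentration grid")
  check_numeric_vec(X_grid, "X_grid", positive = TRUE)
  v_int <- as.numeric(integrated_velocity(model, X_grid))
  v_hin <- predict_vesilind(model$vesilind, X_grid)
  data.frame(X = X_grid,
             flux = (v_int + u) * X_grid,
             flux_hindered = (v_hin + u) * X_grid)
}

golden_min <- function(f, lo, hi, tol = 1e-8) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d)
  while (abs(b - a) > tol * (abs(a) + abs(b) + 1)) {
    if (fc < fd) { b <- d; d <- c_; fd <- fc; c_ <- b - gr * (b - a); fc <- f(c_) }
    else { a <- c_; c_ <- d; fc <- fd; d <- a + gr * (b - a); fd <- f(d) }
  }
  x <- (a + b) / 2
  list(x = x, f = f(x))
}

#' Limiting solids flux
#'
#' The interior minimum of the total flux over concentrations above the
#' compression onset limits the solids loading a settler can pass. Found on
#' a grid and refined by golden-section search, for both the integrated and
#' the hindered-only variant; the relative overestimation
#' `(G_hindered - G_integrated) / G_integrated` is reported.
#'
#' @param model An [integrated_settling_model()].
#' @param u Underflow velocity in m/h, `> 0`.
#' @param X_max Upper concentration bound of the search in g/L; default
#'   `max(3 * X_c, 20)`.
#' @param n_grid Grid size for bracketing, default 400.
#' @return A list with `integrated` and `hindered` (each `list(flux, X)`) and
#'   `overestimate` (relative, dimensionless). A minimum on the search
#'   boundary triggers a `boundary_minimum_warning`.
#' @export
limiting_flux <- function(model, u, X_max = NULL, n_grid = 400L) {
  if (!inherits(model, "integrated_settling_model"))
    sf_error("validation_error", "`model` must be an integrated_settling_model")
  check_number(u, "u", positive = TRUE)
  lo <- max(model$X_c, model$compression$X0) * (1 + 1e-9)
  X_max <- X_max %||% max(3 * model$X_c, 20)
  if (X_max <= lo) sf_error("validation_error", "X_max must exceed X_c")
  grid <- seq(lo, X_max, length.out = n_grid)
  one <- function(fluxfun) {
    g <- fluxfun(grid)
    i <- which.min(g)
    if (i == 1L || i == n_grid) {
      sf_warn("boundary_minimum_warning",
              "flux minimum lies on the search boundary; no interior limiting flux")
      return(list(flux = g[i], X = grid[i]))
    }
    opt <- golden_min(fluxfun, grid[i - 1L], grid[i + 1L])
    list(flux = opt$f, X = opt$x)
  }
  f_int <- function(X) (as.numeric(integrated_velocity(model, X)) + u) * X
  f_hin <- function(X) (predict_vesilind(model$vesilind, X) + u) * X
  res_int <- one(f_int)
  res_hin <- one(f_hin)
  list(integrated = res_int, hindered = res_hin,
       overestimate = (res_hin$flux - res_int$flux) / res_int$flux)
}
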