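# Power-law thickening model for the bottom sludge concentration in a
# secondary clarifier: X_d(t_s) = a * t_s^b, with a in g/L (the concentration
# reached after 1 min of thickening) and b dimensionless. The model is
# calibrated from batch thickening tests and drives the sludge-blanket mass
# balance x * X_d = x0 * X0 and the return-sludge concentration X_r = k * X_d.

#' Construct a thickening-test curve
#'
#' A thickening curve holds the measured bottom sludge concentration over
#' thickening time, as recorded at the base of a settling column. Times are
#' minutes, concentrations g/L.
#'
#' @param times Numeric vector of thickening times in minutes, strictly
#'   increasing, all `>= 0`.
#' @param concentrations Numeric vector of bottom concentrations in g/L,
#'   all `> 0`, same length as `times`.
#' @param plant_id Optional label for the plant/test the curve comes from.
#' @param X0 Optional initial (feed) sludge concentration in g/L; used as a
#'   physical floor on predictions and in the mass balance.
#' @param x0 Optional initial sludge-blanket height in m.
#' @return An object of class `thickening_curve`.
#' @export
#' @examples
#' tc <- thickening_curve(c(1, 10, 90), c(6.6, 7.3, 8.1), plant_id = "demo")
thickening_curve <- function(times, concentrations, plant_id = NULL,
                             X0 = NULL, x0 = NULL) {
  check_numeric_vec(times, "times")
  check_numeric_vec(concentrations, "concentrations", positive = TRUE)
  if (length(times) != length(concentrations))
    sf_error("validation_error", "`times` and `concentrations` differ in length")
  if (any(times < 0))
    sf_error("validation_error", "`times` must be >= 0 minutes")
  check_strictly_increasing(times, "times")
  if (!is.null(X0)) check_number(X0, "X0", positive = TRUE)
  if (!is.null(x0)) check_number(x0, "x0", positive = TRUE)
  structure(
    list(times = as.numeric(times),
         concentrations = as.numeric(concentrations),
         plant_id = plant_id, X0 = X0, x0 = x0),
    class = "thickening_curve"
  )
}

#' @export
print.thickening_curve <- function(x, ...) {
  cat("Thickening curve", if (!is.null(x$plant_id)) paste0("[", x$plant_id, "]"),
      "\n  n =", length(x$times), "points,",
      sprintf("t = %g-%g min, X_d = %.3g-%.3g g/L\n",
              min(x$times), max(x$times),
              min(x$concentrations), max(x$concentrations)))
  if (!is.null(x$X0)) cat("  X0 =", x$X0, "g/L\n")
  if (!is.null(x$x0)) cat("  x0 =", x$x0, "m\n")
  invisible(x)
}

new_power_law_fit <- function(a, b, r_squared, p_value, n_points,
                              scale = "log-log", se = c(NA_real_, NA_real_)) {
  structure(
    list(a = a, b = b, r_squared = r_squared, p_value = p_value,
         n_points = n_points, scale = scale, se = se),
    class = "power_law_fit"
  )
}

#' Fit the power-law thickening model
#'
#' Calibrates `X_d = a * t_s^b` by ordinary least squares on
#' `ln(X_d) ~ ln(t_s)`, which is exact under multiplicative (lognormal)
#' noise — the natural noise model for concentration measurements. Points at
#' `t_s = 0` are excluded (the power law is degenerate there). R-squared and
#' the two-sided t-test p-value for the slope are reported on the fitted
#' (log-log) scale. An optional nonlinear refinement re-minimizes squared
#' error on the original scale, initialized from the log-log solution.
#'
#' A fitted `b` outside `(0, 1)` is physically questionable for thickening
#' and triggers a warning but is never clamped.
#'
#' @param curve A [thickening_curve()].
#' @param refine If `TRUE`, refine `(a, b)` by nonlinear least squares on the
#'   original scale (`stats::nls`); diagnostics stay on the log-log scale.
#' @return A `power_law_fit` with fields `a` (g/L), `b`, `r_squared`,
#'   `p_value`, `n_points`, `scale`, and `se` (standard errors of
#'   `ln a` and `b` on the fitting scale).
#' @export
#' @examples
#' tc <- thickening_curve(c(1, 10, 100), 10 * c(1, 10, 100)^0.05)
#' fit_power_law(tc)
fit_power_law <- function(curve, refine = FALSE) {
  if (!inherits(curve, "thickening_curve"))
    sf_error("validation_error", "`curve` must be a thickening_curve")
  keep <- curve$times > 0
  if (sum(keep) < 3L)
    sf_error("insufficient_data_error",
             "need at least 3 points with t_s > 0 to fit the power law")
  lt <- log(curve$times[keep])
  lx <- log(curve$concentrations[keep])
  fit <- stats::lm(lx ~ lt)
  cf <- stats::coef(fit)
  a <- exp(unname(cf[1]))
  b <- unname(cf[2])
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  # perfect or flat fits have zero residual variance; the t-test is undefined
  se_b <- sm$coefficients[2, 2]
  p <- if (is.finite(se_b) && se_b > 0) sm$coefficients[2, 4] else NA_real_
  if (!is.nan(r2) && is.na(r2)) r2 <- NA_real_
  if (is.nan(r2)) r2 <- NA_real_
  scale <- "log-log"
  if (refine) {
    nl <- tryCatch(
      stats::nls(x ~ a * t^b,
                 data = data.frame(t = curve$times[keep],
                                   x = curve$concentrations[keep]),
                 start = list(a = a, b = b)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf2 <- stats::coef(nl)
      a <- unname(cf2["a"]); b <- unname(cf2["b"])
      scale <- "nonlinear"
    }
  }
  if (is.finite(b) && (b <= 0 || b >= 1))
    sf_warn("parameter_range_warning",
            sprintf("fitted b = %.4g lies outside (0, 1); thickening power laws are expected inside", b))
  new_power_law_fit(a = a, b = b, r_squared = r2, p_value = p,
                    n_points = sum(keep), scale = scale,
                    se = unname(sm$coefficients[, 2]))
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law thickening fit (%s scale)\n", x$scale))
  cat(sprintf("  X_d = %.4g * t_s^%.4g   [a g/L at 1 min, t_s min]\n", x$a, x$b))
  cat(sprintf("  R^2 = %.4g, slope p = %.3g, n = %d\n",
              x$r_squared, x$p_value, x$n_points))
  invisible(x)
}

resolve_fit <- function(fit) {
  if (inherits(fit, "power_law_fit")) return(fit)
  if (is.list(fit) && !is.null(fit$a) && !is.null(fit$b)) return(fit)
  sf_error("validation_error", "`fit` must be a power_law_fit (or a list with a, b)")
}

#' Predict the bottom sludge concentration
#'
#' Evaluates `X_d = a * t_s^b` (g/L). Predictions below the feed
#' concentration `X0` are physically impossible (the blanket cannot be more
#' dilute than its feed), so when `X0` is supplied they are clamped to `X0`
#' and flagged via the `"clamped"` attribute.
#'
#' @param fit A `power_law_fit` (or list with `a`, `b`).
#' @param t_s Thickening time(s) in minutes, all `>= 1` (the model's scale is
#'   anchored at 1 min; below that the power law is unvalidated).
#' @param X0 Optional feed concentration floor in g/L.
#' @return Numeric vector of concentrations (g/L) with logical attribute
#'   `"clamped"` marking floored entries.
#' @export
predict_bottom_concentration <- function(fit, t_s, X0 = NULL) {
  fit <- resolve_fit(fit)
  check_numeric_vec(t_s, "t_s")
  if (any(t_s < 1))
    sf_error("domain_error", "t_s must be >= 1 min for the thickening model")
  xd <- fit$a * t_s^fit$b
  clamped <- rep(FALSE, length(xd))
  if (!is.null(X0)) {
    check_number(X0, "X0", positive = TRUE)
    clamped <- xd < X0
    xd[clamped] <- X0
  }
  attr(xd, "clamped") <- clamped
  xd
}

#' Sludge-blanket height from the thickening mass balance
#'
#' The compression zone is assumed homogeneous, so the blanket obeys
#' `x * X_d = x0 * X0` at all times: `x(t_s) = x0 * X0 / (a * t_s^b)`.
#'
#' @inheritParams predict_bottom_concentration
#' @param x0 Initial blanket height in m.
#' @param X0 Initial (feed) concentration in g/L.
#' @return Heights in m (never exceeding `x0`, since predictions are floored
#'   at `X0`).
#' @export
sludge_height <- function(fit, x0, X0, t_s) {
  check_number(x0, "x0", positive = TRUE)
  check_number(X0, "X0", positive = TRUE)
  xd <- predict_bottom_concentration(fit, t_s, X0 = X0)
  x0 * X0 / as.numeric(xd)
}

#' Sensitivity of the predicted concentration to the exponent b
#'
#' For `X_d = a * t_s^b` the relative sensitivity
#' `S = (dX_d/db) * (b / X_d)` has the closed form `S = b * ln(t_s)`.
#' Small S justifies using a single fleet-wide mean exponent: at the mean
#' `b = 0.0465` the sensitivity stays below 0.2 for thickening times up to
#' about an hour and vanishes as `t_s` approaches 1 min.
#'
#' @param fit A `power_law_fit`, or a bare numeric exponent `b`.
#' @param t_s Thickening time(s) in minutes, `>= 1`.
#' @return Dimensionless sensitivity, same length as `t_s`.
#' @export
sensitivity_to_b <- function(fit, t_s) {
  b <- if (is.numeric(fit) && length(fit) == 1L) fit else resolve_fit(fit)$b
  check_numeric_vec(t_s, "t_s")
  if (any(t_s < 1))
    sf_error("domain_error", "t_s must be >= 1 min")
  b * log(t_s)
}

#' Return-sludge withdrawal specification
#'
#' Turbulence at the clarifier bottom dilutes the withdrawn sludge relative
#' to the modelled bottom concentration: `X_r = k * X_d` with `k` set by the
#' withdrawal practice — `k = 0.7` for scraped bottoms, `k` in 0.5–0.7 for
#' suction withdrawal.
#'
#' @param method `"scrape"` or `"suction"`.
#' @param k Withdrawal efficiency in (0, 1]. Forced to 0.7 for `"scrape"`;
#'   must lie in `[0.5, 0.7]` for `"suction"` (default 0.7).
#' @return An object of class `return_sludge_spec`.
#' @export
return_sludge_spec <- function(method = c("scrape", "suction"), k = NULL) {
  method <- match.arg(method)
  if (method == "scrape") {
    if (!is.null(k) && k != 0.7)
      sf_error("validation_error", "scraped withdrawal fixes k = 0.7")
    k <- 0.7
  } else {
    k <- k %||% 0.7
    check_number(k, "k", positive = TRUE)
    if (k < 0.5 || k > 0.7)
      sf_error("validation_error", "suction withdrawal requires k in [0.5, 0.7]")
  }
  structure(list(k = k, method = method), class = "return_sludge_spec")
}

#' Return sludge concentration
#'
#' `X_r = k * X_d` in g/L.
#'
#' @param X_d Bottom sludge concentration(s) in g/L, `> 0`.
#' @param spec A [return_sludge_spec()], or a bare numeric `k` in (0, 1].
#' @return Return sludge concentration(s) in g/L.
#' @export
#' @examples
#' return_concentration(6.600, return_sludge_spec("scrape")) # 4.620 g/L
return_concentration <- function(X_d, spec) {
  check_numeric_vec(X_d, "X_d", positive = TRUE)
  k <- if (inherits(spec, "return_sludge_spec")) spec$k else spec
  check_number(k, "k")
  if (k <= 0 || k > 1)
    sf_error("validation_error", "k must lie in (0, 1]")
  k * X_d
}
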