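# Graphical detection of the compression onset in a batch settling curve:
# the intersection of the settling curve with the bisector of the angle
# formed by the tangents to the hindered and compression zones. Angles are
# not affine-invariant, so the construction is carried out in fixed
# normalized coordinates (t / t_max, h / x0), mirroring how the curve is
# conventionally plotted.

# unit bisector direction at the tangent vertex, in normalized coordinates.
# M1: hindered tangent slope (normalized), direction taken backward in time;
# M2: compression tangent slope, direction taken forward in time.
bisector_direction <- function(M1, M2) {
  u1 <- c(-1, -M1); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(1, M2); u2 <- u2 / sqrt(sum(u2^2))
  d <- u1 + u2
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12)
    sf_error("no_onset_error", "tangents are anti-parallel; no interior angle")
  d / nd
}

# tangent to the compression zone: linear fit to the points in the last
# `frac` of the log-time range (at least min_window points)
compression_tangent <- function(curve, frac = 0.25, min_window = 4L) {
  t <- curve$times; h <- curve$heights
  pos <- which(t > 0)
  if (length(pos) < min_window)
    sf_error("no_onset_error", "too few positive-time points for a compression tangent")
  lt <- log(t[pos])
  cut <- max(lt) - frac * (max(lt) - min(lt))
  idx <- pos[lt >= cut]
  if (length(idx) < min_window) idx <- utils::tail(pos, min_window)
  c(window_linfit(t[idx], h[idx]), list(from = idx[1], to = idx[length(idx)]))
}

#' Detect the compression onset in a batch settling curve
#'
#' Locates where hindered settling hands over to compression by the
#' bisector-of-tangents construction: (1) the hindered tangent is the
#' straight early segment found by [extract_hindered_velocity()]; (2) the
#' compression tangent is a linear fit to the final quarter of the record in
#' log-time; (3) in normalized coordinates `(t/t_max, h/x0)` the interior
#' angle bisector at the tangents' intersection is cast toward the curve;
#' (4) its crossing with the piecewise-linear interpolated curve gives the
#' onset time `t_c` and height `h_c`, and the mass balance converts the
#' height to the onset concentration `X_c = x0 X0 / h_c`.
#'
#' @param curve A [batch_settling_curve()].
#' @param min_window,r2_min Passed to the hindered-zone search.
#' @param tail_frac Fraction of the log-time range used for the compression
#'   tangent (default 0.25).
#' @return An `onset_estimate`: list with `t_c` (min), `h_c` (m), `X_c`
#'   (g/L) and `diagnostics` (tangent slopes, windows, vertex).
#' @export
detect_compression_onset <- function(curve, min_window = 4L, r2_min = 0.95,
                                     tail_frac = 0.25) {
  if (!inherits(curve, "batch_settling_curve"))
    sf_error("validation_error", "`curve` must be a batch_settling_curve")
  t <- curve$times; h <- curve$heights
  n <- length(t)
  if (n < 8L)
    sf_error("insufficient_data_error", "need at least 8 points for onset detection")

  vh <- tryCatch(extract_hindered_velocity(curve, min_window, r2_min),
                 error = function(e) {
                   if (inherits(e, "no_linear_zone_error"))
                     sf_error("no_onset_error", "no hindered (linear) zone found")
                   stop(e)
                 })
  m1 <- attr(vh, "slope_m_min"); c1 <- attr(vh, "intercept_m")
  ct <- compression_tangent(curve, tail_frac, min_window)
  m2 <- ct$slope; c2 <- ct$intercept

  # a genuine compression zone must be distinctly flatter than the hindered
  # line; a single straight line (or a flat record) has no onset
  whole <- window_linfit(t, h)
  if (whole$r_squared >= 0.999 || abs(m1 - m2) < 1e-9 ||
      abs(m1 - m2) < 0.05 * abs(m1))
    sf_error("no_onset_error", "curve has no distinct compression zone")

  t_v <- (c2 - c1) / (m1 - m2)
  h_v <- c1 + m1 * t_v
  t_max <- max(t); x0 <- curve$x0

  # normalized coordinates
  Tn <- t / t_max; Hn <- h / x0
  V <- c(t_v / t_max, h_v / x0)
  d <- bisector_direction(m1 * t_max / x0, m2 * t_max / x0)

  # signed perpendicular offset of every curve point from the bisector line,
  # and along-ray coordinate; crossing = sign change with positive projection
  px <- Tn - V[1]; py <- Hn - V[2]
  offset <- d[1] * py - d[2] * px
  along <- d[1] * px + d[2] * py
  hit <- NULL
  sgn <- sign(offset)
  for (i in seq_len(n - 1L)) {
    if (sgn[i] == 0) { if (along[i] >= 0) { hit <- c(Tn[i], Hn[i]); break } else next }
    if (sgn[i] * sgn[i + 1L] < 0) {
      w <- offset[i] / (offset[i] - offset[i + 1L])
      P <- c(Tn[i] + w * (Tn[i + 1L] - Tn[i]), Hn[i] + w * (Hn[i + 1L] - Hn[i]))
      if ((P[1] - V[1]) * d[1] + (P[2] - V[2]) * d[2] >= 0) { hit <- P; break }
    }
  }
  if (is.null(hit))
    sf_error("no_intersection_error",
             "angle bisector does not intersect the settling curve in range")

  t_c <- hit[1] * t_max
  h_c <- hit[2] * x0
  X_c <- x0 * curve$X0 / h_c
  structure(
    list(t_c = t_c, h_c = h_c, X_c = X_c,
         diagnostics = list(
           hindered = list(slope_m_min = m1, intercept_m = c1,
                           window = attr(vh, "window"),
                           r_squared = attr(vh, "r_squared")),
           compression = list(slope_m_min = m2, intercept_m = c2,
                              window = c(ct$from, ct$to),
                              r_squared = ct$r_squared),
           vertex = c(t = t_v, h = h_v),
           bisector_direction = d)),
    class = "onset_estimate"
  )
}

#' @export
print.onset_estimate <- function(x, ...) {
  cat(sprintf("Compression onset: t_c = %.3g min, h_c = %.4g m, X_c = %.4g g/L\n",
              x$t_c, x$h_c, x$X_c))
  invisible(x)
}
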