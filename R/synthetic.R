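# Seeded generators emulating the data the model family consumes: power-law
# thickening curves with multiplicative lognormal noise, two-phase batch
# settling curves (hindered line joined continuously to the mass-balance
# compression tail), cross-plant SVI panels with log-linear structure, and
# synthetic floc images with controllable boundary roughness. Every
# generator records its ground truth so recovery tests can close the loop,
# and is bit-reproducible under a fixed seed (RNG state is restored on
# exit).

#' Generate a thickening-test curve
#'
#' `X_d(t_i) = a t_i^b exp(eps_i)` with `eps_i ~ N(0, noise_level)`;
#' multiplicative lognormal noise keeps concentrations positive, matching
#' instrument behaviour. Times are log-spaced over `time_range`, mirroring
#' the information content of a power law.
#'
#' @param a,b True power-law parameters (g/L, dimensionless).
#' @param n_points Number of samples, `>= 3`; default 30.
#' @param time_range Minutes, default `c(1, 90)` (the standard 90-min test).
#' @param noise_level Relative noise (sd of `eps`), `>= 0`; default 0.01.
#' @param seed Integer seed.
#' @param plant_id,X0,x0 Passed through to [thickening_curve()].
#' @return A `thickening_curve` with attribute `"ground_truth"`
#'   (`list(a, b)`).
#' @export
gen_thickening_curve <- function(a, b, n_points = 30L, time_range = c(1, 90),
                                 noise_level = 0.01, seed = 1L,
                                 plant_id = "synthetic", X0 = NULL, x0 = NULL) {
  check_number(a, "a", positive = TRUE)
  check_number(b, "b")
  check_number(noise_level, "noise_level")
  if (noise_level < 0) sf_error("validation_error", "noise_level must be >= 0")
  if (n_points < 3L) sf_error("validation_error", "n_points must be >= 3")
  if (length(time_range) != 2L || time_range[1] <= 0 || diff(time_range) <= 0)
    sf_error("validation_error", "time_range must be increasing and positive")
  times <- exp(seq(log(time_range[1]), log(time_range[2]), length.out = n_points))
  eps <- withr::with_seed(seed, stats::rnorm(n_points, 0, noise_level))
  conc <- a * times^b * exp(eps)
  out <- thickening_curve(times, conc, plant_id = plant_id, X0 = X0, x0 = x0)
  attr(out, "ground_truth") <- list(a = a, b = b)
  out
}

#' Generate a two-phase batch settling curve
#'
#' Hindered phase: `h(t) = x0 - v t` up to the transition time `t_star`;
#' compression phase: the mass-balance tail `h(t) = x0 X0 / (a t^b)`, with
#' `a` solved so the branches meet continuously at `t_star`. Additive
#' Gaussian noise models the reading error of an interface height.
#'
#' @param v Hindered settling velocity in m/h, `>= 0`.
#' @param t_star Transition time in minutes, inside `time_range`.
#' @param b Compression-tail exponent, in (0, 1); default 0.0465.
#' @param x0 Initial height in m, default 1.
#' @param X0 Initial concentration in g/L, default 6.6.
#' @param n_points Samples, default 40.
#' @param time_range Minutes, default `c(0, 90)`.
#' @param noise_level Additive height noise sd in m, default 0.002.
#' @param seed Integer seed.
#' @return A `batch_settling_curve` with attribute `"ground_truth"`
#'   (`list(v, t_star, a, b, X_star)` where `X_star` is the concentration at
#'   the constructed transition).
#' @export
gen_batch_settling_curve <- function(v, t_star, b = 0.0465, x0 = 1, X0 = 6.6,
                                     n_points = 40L, time_range = c(0, 90),
                                     noise_level = 0.002, seed = 1L) {
  check_number(v, "v"); check_number(t_star, "t_star", positive = TRUE)
  check_number(b, "b", positive = TRUE)
  check_number(x0, "x0", positive = TRUE)
  check_number(X0, "X0", positive = TRUE)
  if (b >= 1) sf_error("validation_error", "b must be < 1")
  if (v < 0) sf_error("validation_error", "v must be >= 0")
  if (t_star <= time_range[1] || t_star >= time_range[2])
    sf_error("validation_error", "t_star must lie inside time_range")
  v_mpm <- v / 60
  h_star <- x0 - v_mpm * t_star
  if (h_star <= 0)
    sf_error("validation_error",
             "hindered branch reaches zero height before t_star")
  a <- x0 * X0 / (h_star * t_star^b)        # continuity at t_star
  times <- seq(time_range[1], time_range[2], length.out = n_points)
  # v = 0 is the degenerate no-settling case: the blanket never thickens and
  # the curve is flat (the continuity construction would otherwise force a
  # spurious decaying tail through x0)
  h <- if (v == 0) rep(x0, n_points) else
    ifelse(times <= t_star,
           x0 - v_mpm * times,
           x0 * X0 / (a * times^b))
  if (noise_level > 0) {
    eps <- withr::with_seed(seed, stats::rnorm(n_points, 0, noise_level))
    h <- pmax(h + eps, 1e-6)
  }
  out <- batch_settling_curve(times, h, X0 = X0, x0 = x0,
                              noise_tol = max(0.02, 5 * noise_level / x0))
  attr(out, "ground_truth") <- list(v = v, t_star = t_star, a = a, b = b,
                                    X_star = x0 * X0 / h_star)
  out
}

#' Generate a cross-plant SVI panel
#'
#' `a_i = (alpha ln(SVI_i) + beta) (1 + eps_i)` with relative Gaussian noise,
#' and `b_i ~ N(b_mean, b_spread)`.
#'
#' @param alpha,beta True link coefficients.
#' @param svi SVI values in mL/g (one per plant).
#' @param noise_level Relative noise on `a`, default 0.02.
#' @param b_mean,b_spread Exponent distribution; defaults 0.0465 and 0.004
#'   (the spread of the built-in calibration panel).
#' @param seed Integer seed.
#' @return A data.frame of plant records with attribute `"ground_truth"`.
#' @export
gen_plant_panel <- function(alpha, beta, svi, noise_level = 0.02,
                            b_mean = 0.0465, b_spread = 0.004, seed = 1L) {
  check_number(alpha, "alpha"); check_number(beta, "beta")
  check_numeric_vec(svi, "svi", positive = TRUE)
  if (noise_level < 0 || b_spread < 0)
    sf_error("validation_error", "noise_level and b_spread must be >= 0")
  n <- length(svi)
  draws <- withr::with_seed(seed, list(
    eps = stats::rnorm(n, 0, noise_level),
    b = stats::rnorm(n, b_mean, b_spread)))
  a <- (alpha * log(svi) + beta) * (1 + draws$eps)
  if (any(a <= 0))
    sf_error("validation_error", "generated a <= 0; adjust alpha/beta/svi")
  out <- data.frame(plant_id = sprintf("plant_%02d", seq_len(n)),
                    svi = svi, a = a, b = draws$b)
  attr(out, "ground_truth") <- list(alpha = alpha, beta = beta, b_mean = b_mean)
  out
}

# radial boundary r(theta) = r0 * (1 + roughness * F(theta)), F a random
# Fourier series normalized to unit sd
floc_radius_profile <- function(r0, roughness, n_harmonics, theta, coefs) {
  if (roughness == 0) return(rep(r0, length(theta)))
  f <- rep(0, length(theta))
  for (k in seq_len(n_harmonics))
    f <- f + coefs$ac[k] * cos(k * theta) + coefs$as[k] * sin(k * theta)
  f <- f / coefs$norm
  pmax(r0 * (1 + roughness * f), 0.2 * r0)
}

#' Generate a synthetic floc image
#'
#' Places `n_flocs` non-overlapping blobs with radial boundaries
#' `r(theta) = r0 (1 + roughness * F(theta))`, `F` a random Fourier series
#' (harmonics 2..`n_harmonics`+1, amplitudes ~ 1/k, normalized to unit sd).
#' `roughness` is the relative sd of the boundary perturbation; 0 gives
#' disks. Optionally `n_border` additional blobs are centred on the image
#' border (truncated flocs that segmentation should discard).
#'
#' @param n_flocs Interior blobs to place.
#' @param radius_range Base radii r0 in px, default `c(5, 25)`.
#' @param roughness Boundary roughness in `[0, 0.5]`, default 0.1.
#' @param img_size `c(rows, cols)`, default `c(256, 256)`.
#' @param n_border Blobs centred on the border, default 0.
#' @param n_harmonics Fourier harmonics, default 8.
#' @param seed Integer seed.
#' @param max_retries Placement attempts per blob, default 200.
#' @return `list(image, truth)`: the image is a numeric matrix (background
#'   0, flocs 255), `truth` a data.frame with per-blob centre, `r0`,
#'   `roughness` and first-order analytic area `pi r0^2 (1 + roughness^2)`.
#' @export
gen_floc_image_set <- function(n_flocs, radius_range = c(5, 25),
                               roughness = 0.1, img_size = c(256L, 256L),
                               n_border = 0L, n_harmonics = 8L, seed = 1L,
                               max_retries = 200L) {
  if (roughness < 0 || roughness > 0.5)
    sf_error("validation_error", "roughness must lie in [0, 0.5]")
  if (n_flocs < 1L) sf_error("validation_error", "n_flocs must be >= 1")
  nr <- img_size[1]; nc <- img_size[2]
  withr::with_seed(seed, {
    img <- matrix(0, nr, nc)
    placed <- data.frame()
    theta_grid <- seq(0, 2 * pi, length.out = 181L)
    draw_coefs <- function() {
      ac <- stats::rnorm(n_harmonics) / seq_len(n_harmonics)
      as <- stats::rnorm(n_harmonics) / seq_len(n_harmonics)
      f <- rep(0, length(theta_grid))
      for (k in seq_len(n_harmonics))
        f <- f + ac[k] * cos(k * theta_grid) + as[k] * sin(k * theta_grid)
      list(ac = ac, as = as, norm = max(stats::sd(f), 1e-9))
    }
    stamp <- function(cy, cx, r0, coefs) {
      rmax <- if (roughness == 0) r0 else
        max(floc_radius_profile(r0, roughness, n_harmonics, theta_grid, coefs))
      lo_r <- max(1L, floor(cy - rmax)); hi_r <- min(nr, ceiling(cy + rmax))
      lo_c <- max(1L, floor(cx - rmax)); hi_c <- min(nc, ceiling(cx + rmax))
      if (lo_r > hi_r || lo_c > hi_c) return()
      rr <- lo_r:hi_r; cc <- lo_c:hi_c
      dy <- matrix(rr - cy, length(rr), length(cc))
      dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
      dist <- sqrt(dy^2 + dx^2)
      ang <- atan2(dy, dx)
      rb <- matrix(floc_radius_profile(r0, roughness, n_harmonics, as.numeric(ang), coefs),
                   length(rr), length(cc))
      inside <- dist <= rb
      img[rr, cc][inside] <<- 255
    }
    place_one <- function(on_border) {
      for (try in seq_len(max_retries)) {
        r0 <- stats::runif(1, radius_range[1], radius_range[2])
        coefs <- draw_coefs()
        rmax <- if (roughness == 0) r0 else
          max(floc_radius_profile(r0, roughness, n_harmonics, theta_grid, coefs))
        if (on_border) {
          side <- sample(4L, 1L)
          cy <- switch(side, 1, nr, stats::runif(1, 2, nr - 1), stats::runif(1, 2, nr - 1))
          cx <- switch(side, stats::runif(1, 2, nc - 1), stats::runif(1, 2, nc - 1), 1, nc)
        } else {
          margin <- rmax + 3
          if (2 * margin >= min(nr, nc)) next
          cy <- stats::runif(1, margin, nr - margin)
          cx <- stats::runif(1, margin, nc - margin)
        }
        ok <- TRUE
        if (nrow(placed)) {
          dd <- sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2)
          if (any(dd < placed$rmax + rmax + 3)) ok <- FALSE
        }
        if (ok) {
          stamp(cy, cx, r0, coefs)
          placed <<- rbind(placed, data.frame(
            cy = cy, cx = cx, r0 = r0, rmax = rmax, border = on_border,
            area_analytic = pi * r0^2 * (1 + roughness^2)))
          return(TRUE)
        }
      }
      FALSE
    }
    for (i in seq_len(n_flocs))
      if (!place_one(FALSE))
        sf_error("placement_error",
                 sprintf("could not place blob %d without overlap after %d tries",
                         i, max_retries))
    for (i in seq_len(n_border))
      if (!place_one(TRUE))
        sf_error("placement_error", "could not place border blob")
    list(image = img, truth = placed)
  })
}
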