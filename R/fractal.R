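# Floc morphometry: segment sludge flocs from a grayscale image, measure
# area / perimeter / volume per floc, and estimate the two-dimensional (D2),
# three-dimensional (D3) and boundary (DB) fractal dimensions from log-log
# scaling of area and volume against perimeter:
#   A ~ P^D2,   V ~ P^D3,   A ~ P^(2/DB).
# Compact flocs have D2 near 2 and DB near 1; loose, porous flocs have
# lower D2 and higher DB.

#' Otsu threshold of a grayscale image
#'
#' Histogram-based global threshold maximizing between-class variance.
#'
#' @param img Numeric matrix of intensities.
#' @param n_bins Histogram resolution, default 256.
#' @return Threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  bin <- pmin(n_bins, floor((v - rng[1]) / diff(rng) * n_bins) + 1L)
  h <- tabulate(bin, n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / n_bins * diff(rng)
}

# connected-component labeling by vectorized flood fill
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      cc <- ((frontier - 1L) %/% nr) + 1L
      nr_ <- rep(r, each = length(dr)) + dr
      nc_ <- rep(cc, each = length(dc)) + dc
      ok <- nr_ >= 1L & nr_ <= nr & nc_ >= 1L & nc_ <= nc
      nb <- (nc_[ok] - 1L) * nr + nr_[ok]
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# 3x3 box filter (zero padding)
box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  out / 9
}

# Marching-squares contour length of a scalar field at a level, with linear
# subpixel interpolation of the crossing points on cell edges. Applied to a
# box-smoothed binary mask this estimates the boundary length with ~1%
# accuracy on digitized disks (a plain binary-mask contour is biased ~7%
# high on smooth shapes).
contour_length <- function(g, level = 0.5) {
  nr <- nrow(g); nc <- ncol(g)
  if (nr < 2L || nc < 2L) return(0)
  v00 <- g[-nr, -nc]; v10 <- g[-nr, -1]; v01 <- g[-1, -nc]; v11 <- g[-1, -1]
  in00 <- v00 >= level; in10 <- v10 >= level
  in01 <- v01 >= level; in11 <- v11 >= level
  code <- in00 + 2L * in10 + 4L * in01 + 8L * in11
  # crossing parameters on the four cell edges (x = column axis, y = row axis)
  tT <- (level - v00) / (v10 - v00)
  tB <- (level - v01) / (v11 - v01)
  tL <- (level - v00) / (v01 - v00)
  tR <- (level - v10) / (v11 - v10)
  dTL <- sqrt(tT^2 + tL^2)
  dTR <- sqrt((1 - tT)^2 + tR^2)
  dTB <- sqrt((tB - tT)^2 + 1)
  dLR <- sqrt(1 + (tR - tL)^2)
  dLB <- sqrt(tB^2 + (1 - tL)^2)
  dRB <- sqrt((1 - tB)^2 + (1 - tR)^2)
  len <- matrix(0, nrow(code), ncol(code))
  pick <- function(case, d) { i <- code == case; len[i] <<- d[i] }
  pick(1L, dTL); pick(14L, dTL)
  pick(2L, dTR); pick(13L, dTR)
  pick(3L, dLR); pick(12L, dLR)
  pick(4L, dLB); pick(11L, dLB)
  pick(5L, dTB); pick(10L, dTB)
  pick(7L, dRB); pick(8L, dRB)
  ctr <- (v00 + v10 + v01 + v11) / 4
  sad <- code == 6L
  if (any(sad))
    len[sad] <- ifelse(ctr[sad] >= level, dTL[sad] + dRB[sad], dTR[sad] + dLB[sad])
  sad <- code == 9L
  if (any(sad))
    len[sad] <- ifelse(ctr[sad] >= level, dTR[sad] + dLB[sad], dTL[sad] + dRB[sad])
  sum(len)
}

# perimeter of one component mask: pad, smooth, contour
component_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0, nr + 4L, nc + 4L)
  p[3:(nr + 2L), 3:(nc + 2L)] <- mask
  contour_length(box3(p), 0.5)
}

#' Segment and measure flocs in a grayscale image
#'
#' Global threshold (Otsu by default), 8-connected component labeling,
#' removal of components touching the image border (they are truncated) and
#' of components below `min_area`. Per floc: area `A` = pixel count,
#' perimeter `P` = subpixel marching-squares contour length of the smoothed
#' component mask, and volume `V` = volume of the area-equivalent sphere,
#' `V = (4/3) pi r_eq^3` with `r_eq = sqrt(A/pi)` (a 2D image carries no
#' direct volume information; the equivalent-sphere model is the documented,
#' replaceable convention here).
#'
#' @param image Numeric matrix (grayscale raster), or path to an ASCII PGM
#'   file (see [read_pgm()]).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold Intensity cutoff when `threshold_method = "fixed"`.
#' @param min_area Minimum component area in px^2, `>= 4`; default 10.
#' @param connectivity 4 or 8 (default 8).
#' @param exclude_border Drop components touching the border (default TRUE).
#' @param scale Physical length per pixel (e.g. um/px), default 1.
#' @param foreground `"bright"` (flocs brighter than background, default) or
#'   `"dark"`.
#' @return A data.frame with columns `floc_id`, `area`, `perimeter`,
#'   `volume`, `n_pixels`. Empty (with an `empty_result_warning`) when no
#'   component survives the filters.
#' @export
measure_flocs <- function(image, threshold_method = c("otsu", "fixed"),
                          threshold = NULL, min_area = 10, connectivity = 8L,
                          exclude_border = TRUE, scale = 1,
                          foreground = c("bright", "dark")) {
  threshold_method <- match.arg(threshold_method)
  foreground <- match.arg(foreground)
  if (is.character(image)) image <- read_pgm(image)
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    sf_error("validation_error", "`image` must be a non-empty numeric matrix")
  if (min_area < 4)
    sf_error("validation_error", "`min_area` must be >= 4 px^2")
  img <- if (foreground == "dark") -image else image
  th <- switch(threshold_method,
               otsu = otsu_threshold(img),
               fixed = {
                 check_number(threshold, "threshold")
                 if (foreground == "dark") -threshold else threshold
               })
  mask <- img > th
  lab <- label_components(mask, connectivity)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  empty <- data.frame(floc_id = character(), area = numeric(),
                      perimeter = numeric(), volume = numeric(),
                      n_pixels = integer())
  if (!length(ids)) {
    sf_warn("empty_result_warning", "no foreground components found")
    return(empty)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  rows <- list()
  for (id in ids) {
    pix <- which(lab == id)
    r <- ((pix - 1L) %% nr) + 1L
    cc <- ((pix - 1L) %/% nr) + 1L
    if (exclude_border && (any(r == 1L | r == nr) || any(cc == 1L | cc == nc)))
      next
    if (length(pix) < min_area) next
    sub <- matrix(0, max(r) - min(r) + 1L, max(cc) - min(cc) + 1L)
    sub[cbind(r - min(r) + 1L, cc - min(cc) + 1L)] <- 1
    A <- length(pix) * scale^2
    P <- component_perimeter(sub) * scale
    r_eq <- sqrt(A / pi)
    rows[[length(rows) + 1L]] <- data.frame(
      floc_id = sprintf("floc_%03d", length(rows) + 1L),
      area = A, perimeter = P, volume = 4 / 3 * pi * r_eq^3,
      n_pixels = length(pix))
  }
  if (!length(rows)) {
    sf_warn("empty_result_warning", "no components survive the area/border filters")
    return(empty)
  }
  do.call(rbind, rows)
}

#' Validate a floc measurement table
#'
#' Checks positivity and the isoperimetric inequality `P^2 >= 4 pi A`
#' (with 2% slack for discretization) for each floc.
#'
#' @param measurements data.frame with columns `area`, `perimeter`, `volume`
#'   (and optionally `floc_id`).
#' @return The validated data.frame.
#' @export
floc_measurements <- function(measurements) {
  if (!is.data.frame(measurements))
    sf_error("validation_error", "`measurements` must be a data.frame")
  need <- c("area", "perimeter", "volume")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    sf_error("format_error",
             paste("missing column(s):", paste(miss, collapse = ", ")))
  for (col in need) check_numeric_vec(measurements[[col]], col, positive = TRUE)
  bad <- measurements$perimeter^2 < 4 * pi * measurements$area * 0.98
  if (any(bad))
    sf_warn("isoperimetric_warning",
            sprintf("%d floc(s) violate P^2 >= 4*pi*A beyond 2%% slack", sum(bad)))
  if (is.null(measurements$floc_id))
    measurements$floc_id <- sprintf("floc_%03d", seq_len(nrow(measurements)))
  measurements
}

#' Fit floc fractal dimensions
#'
#' Log-log regressions against perimeter: `D2` is the OLS slope of
#' `log A ~ log P`, `D3` the slope of `log V ~ log P`, and `DB = 2 / slope`
#' from the same area-perimeter regression (`A ~ P^(2/DB)`). `D2` and `DB`
#' are algebraically linked under a single regression (`D2 * DB = 2`); they
#' are still reported side by side because field practice derives them from
#' differently operationalized perimeters and quotes both.
#'
#' @param measurements A table accepted by [floc_measurements()], at least 5
#'   flocs; a perimeter spread under one decade triggers a warning.
#' @return A `fractal_estimates`: `D2`, `D3`, `DB`, standard errors (delta
#'   method for `DB`), `n_flocs`.
#' @export
fit_fractal_dimensions <- function(measurements) {
  m <- floc_measurements(measurements)
  if (nrow(m) < 5L)
    sf_error("insufficient_data_error", "need at least 5 floc measurements")
  if (diff(range(m$perimeter)) == 0)
    sf_error("insufficient_spread_error", "all perimeters are equal")
  if (diff(range(log10(m$perimeter))) < 1)
    sf_warn("single_decade_warning",
            "perimeters span less than one decade; fitted slopes are fragile")
  lp <- log(m$perimeter)
  f2 <- stats::lm(log(m$area) ~ lp)
  f3 <- stats::lm(log(m$volume) ~ lp)
  s2 <- unname(stats::coef(f2)[2]); s3 <- unname(stats::coef(f3)[2])
  se2 <- suppressWarnings(summary(f2))$coefficients[2, 2]
  se3 <- suppressWarnings(summary(f3))$coefficients[2, 2]
  structure(
    list(D2 = s2, D3 = s3, DB = 2 / s2,
         se = c(D2 = se2, D3 = se3, DB = 2 * se2 / s2^2),
         n_flocs = nrow(m)),
    class = "fractal_estimates"
  )
}

#' @export
print.fractal_estimates <- function(x, ...) {
  cat(sprintf("Fractal estimates (n = %d flocs):\n", x$n_flocs))
  cat(sprintf("  D2 = %.3f (se %.3f), D3 = %.3f (se %.3f), DB = %.3f (se %.3f)\n",
              x$D2, x$se["D2"], x$D3, x$se["D3"], x$DB, x$se["DB"]))
  invisible(x)
}

#' Trend of fractal dimensions across plants versus SVI
#'
#' OLS slope (with two-sided p-value) of each fractal dimension against SVI
#' over a panel of plants. Sludge that settles poorly (high SVI) tends to
#' have looser flocs: D2 and D3 decrease with SVI while DB increases. This
#' is a descriptive regression, not a causal claim.
#'
#' @param panel data.frame with columns `svi`, `D2`, `D3`, `DB`
#'   (>= 3 plants).
#' @return data.frame with columns `dimension`, `slope`, `p_value`, `sign`.
#' @export
svi_fractal_trend <- function(panel) {
  if (!is.data.frame(panel))
    sf_error("validation_error", "`panel` must be a data.frame")
  need <- c("svi", "D2", "D3", "DB")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    sf_error("format_error",
             paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(panel) < 3L)
    sf_error("insufficient_data_error", "need at least 3 plants")
  out <- lapply(c("D2", "D3", "DB"), function(d) {
    fit <- stats::lm(panel[[d]] ~ panel$svi)
    sm <- suppressWarnings(summary(fit))
    slope <- unname(stats::coef(fit)[2])
    se <- sm$coefficients[2, 2]
    p <- if (is.finite(se) && se > 0) sm$coefficients[2, 4] else NA_real_
    data.frame(dimension = d, slope = slope, p_value = p,
               sign = sign(slope))
  })
  do.call(rbind, out)
}
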