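# Readers and writers for the package's on-disk dialects:
#  - time-series CSV (`time_min,conc_g_L` for thickening tests,
#    `time_min,height_m` for batch settling tests), `#` comments allowed;
#  - fitted models as JSON documents with explicit units and provenance;
#  - grayscale rasters as ASCII PGM (P2).
# Canonical units everywhere: minutes, m, g/L, mL/g, m/h. Decimal points
# only (no locale commas).

ts_columns <- list(
  thickening = c("time_min", "conc_g_L"),
  batch = c("time_min", "height_m")
)

#' Read a time-series CSV
#'
#' @param path CSV file with header `time_min,conc_g_L` (thickening) or
#'   `time_min,height_m` (batch); lines starting with `#` are skipped.
#' @param kind `"thickening"` or `"batch"`.
#' @param X0,x0 Metadata required for `kind = "batch"` (initial
#'   concentration g/L and height m), optional for thickening curves.
#' @param plant_id Optional label.
#' @return A `thickening_curve` or `batch_settling_curve`.
#' @export
read_timeseries_csv <- function(path, kind = c("thickening", "batch"),
                                X0 = NULL, x0 = NULL, plant_id = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    sf_error("format_error", paste("file not found:", path))
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- ts_columns[[kind]]
  miss <- setdiff(need, names(df))
  if (length(miss))
    sf_error("format_error",
             sprintf("missing column(s) in %s: %s", path,
                     paste(miss, collapse = ", ")))
  if (kind == "thickening") {
    thickening_curve(df$time_min, df$conc_g_L, plant_id = plant_id,
                     X0 = X0, x0 = x0)
  } else {
    if (is.null(X0) || is.null(x0))
      sf_error("validation_error", "batch curves require X0 (g/L) and x0 (m)")
    batch_settling_curve(df$time_min, df$height_m, X0 = X0, x0 = x0)
  }
}

#' Write a curve to CSV
#'
#' Inverse of [read_timeseries_csv()]; numbers are written at full double
#' precision so a round trip reproduces the curve to 1e-15.
#'
#' @param curve A `thickening_curve` or `batch_settling_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(curve, path) {
  if (inherits(curve, "thickening_curve")) {
    df <- data.frame(time_min = curve$times, conc_g_L = curve$concentrations)
  } else if (inherits(curve, "batch_settling_curve")) {
    df <- data.frame(time_min = curve$times, height_m = curve$heights)
  } else {
    sf_error("validation_error", "`curve` must be a thickening or batch curve")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(df, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ",")), con)
  invisible(path)
}

model_type <- function(model) {
  for (cl in c("power_law_fit", "svi_link_model", "vesilind_fit",
               "compression_law", "integrated_settling_model"))
    if (inherits(model, cl)) return(cl)
  sf_error("validation_error", "unsupported model class for JSON serialization")
}

model_units <- list(
  power_law_fit = list(a = "g/L", t_s = "min"),
  svi_link_model = list(a = "g/L", svi = "mL/g"),
  vesilind_fit = list(v0 = "m/h", n = "L/g"),
  compression_law = list(a = "g/L", x0 = "m", X0 = "g/L", velocity = "m/h"),
  integrated_settling_model = list(velocity = "m/h", X = "g/L")
)

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Serialize a fitted model to JSON
#'
#' The document carries the model type, its fields, explicit units, a
#' provenance tag and the package version, so a fitted artifact is
#' self-describing and round-trips losslessly through [read_model_json()].
#'
#' @param model A fitted model object (`power_law_fit`, `svi_link_model`,
#'   `vesilind_fit`, `compression_law`, `integrated_settling_model`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  type <- model_type(model)
  fields <- strip_class(unclass(model))
  if (type == "integrated_settling_model") {
    fields$vesilind <- strip_class(unclass(model$vesilind))
    fields$compression <- strip_class(unclass(model$compression))
  }
  doc <- list(
    type = type,
    toolkit = "settleflux",
    version = as.character(utils::packageVersion("settleflux")),
    units = model_units[[type]],
    provenance = model$provenance %||% "fitted",
    fields = fields
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

rebuild_model <- function(type, f) {
  switch(type,
    power_law_fit = new_power_law_fit(f$a, f$b, f$r_squared %||% NA_real_,
                                      f$p_value %||% NA_real_,
                                      f$n_points %||% NA_integer_,
                                      f$scale %||% "log-log",
                                      unlist(f$se) %||% c(NA_real_, NA_real_)),
    svi_link_model = new_svi_link_model(f$alpha, f$beta,
                                        f$r_squared %||% NA_real_,
                                        f$p_value %||% NA_real_,
                                        unlist(f$svi_validity),
                                        unlist(f$xd_validity),
                                        f$mean_b %||% NA_real_,
                                        f$log_base %||% "natural",
                                        f$provenance %||% "refit",
                                        f$note),
    vesilind_fit = structure(list(v0 = f$v0, n = f$n,
                                  r_squared = f$r_squared %||% NA_real_,
                                  n_points = f$n_points %||% NA_integer_),
                             class = "vesilind_fit"),
    compression_law = compression_law(f$a, f$b, f$x0, f$X0),
    integrated_settling_model = integrated_settling_model(
      rebuild_model("vesilind_fit", f$vesilind),
      rebuild_model("compression_law", f$compression),
      f$X_c),
    sf_error("schema_error", paste("unknown model type:", type))
  )
}

#' Read a fitted model from JSON
#'
#' Validates the schema (type, units, fields); a missing unit block is a
#' schema error, a version mismatch only a warning.
#'
#' @param path JSON file written by [write_model_json()].
#' @return The reconstructed model object, with the stored provenance
#'   available as attribute `"provenance"`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path))
    sf_error("format_error", paste("file not found:", path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    sf_error("schema_error", paste("corrupted JSON:", conditionMessage(e))))
  for (key in c("type", "units", "fields"))
    if (is.null(doc[[key]]))
      sf_error("schema_error", sprintf("missing `%s` field in model document", key))
  ver <- doc$version %||% "unknown"
  cur <- as.character(utils::packageVersion("settleflux"))
  if (!identical(ver, cur))
    sf_warn("version_warning",
            sprintf("model written by toolkit %s, reading with %s", ver, cur))
  model <- rebuild_model(doc$type, doc$fields)
  attr(model, "provenance") <- doc$provenance %||% "fitted"
  model
}

#' Read an ASCII PGM (P2) grayscale image
#'
#' Plain-text portable graymap; the package's raster interchange format.
#'
#' @param path PGM file.
#' @return Numeric matrix of intensities.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path))
    sf_error("format_error", paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  tok <- scan(text = paste(lines, collapse = " "), what = character(),
              quiet = TRUE)
  if (length(tok) < 4L || tok[1] != "P2")
    sf_error("format_error", "not an ASCII PGM (P2) file")
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != nr * nc)
    sf_error("format_error",
             sprintf("expected %d pixels, found %d", nr * nc, length(vals)))
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Write an ASCII PGM (P2) grayscale image
#'
#' @param img Numeric matrix; values are rounded and clipped to
#'   `[0, maxval]`.
#' @param path Output file.
#' @param maxval Maximum gray value, default 255.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  if (!is.matrix(img)) sf_error("validation_error", "`img` must be a matrix")
  m <- pmin(pmax(round(img), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a JSON run configuration
#'
#' Recognized keys: `units` (subset of time=min, length=m,
#' concentration=g/L, svi=mL/g, velocity=m/h), `k`, `method`, `x0`, `X0`,
#' `svi`, `preset` (`"printed"` or `"refit"`), `seed`, `verbosity`. Unknown
#' keys are rejected so typos cannot silently change a run.
#'
#' @param path JSON file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    sf_error("format_error", paste("file not found:", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("units", "k", "method", "x0", "X0", "svi", "preset", "seed",
               "verbosity", "plant_id")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    sf_error("validation_error",
             paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  canonical <- c(time = "min", length = "m", concentration = "g/L",
                 svi = "mL/g", velocity = "m/h")
  if (!is.null(cfg$units)) {
    bad <- names(cfg$units)[!mapply(identical, cfg$units,
                                    as.list(canonical[names(cfg$units)]))]
    if (length(bad) || any(!names(cfg$units) %in% names(canonical)))
      sf_error("validation_error",
               "units must come from the canonical set: min, m, g/L, mL/g, m/h")
  }
  if (!is.null(cfg$preset) && !cfg$preset %in% c("printed", "refit"))
    sf_error("validation_error", "preset must be 'printed' or 'refit'")
  cfg
}
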