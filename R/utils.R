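# Internal helpers: typed conditions and small validators shared across the
# package. All user-facing errors carry a condition class so callers (and the
# CLI) can distinguish validation problems from usage problems.

sf_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "settleflux_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

sf_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "settleflux_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    sf_error("validation_error", sprintf("`%s` must be a single number", name))
  if (finite && !is.finite(x))
    sf_error("validation_error", sprintf("`%s` must be finite", name))
  if (positive && x <= 0)
    sf_error("validation_error", sprintf("`%s` must be > 0", name))
  invisible(x)
}

check_numeric_vec <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x))
    sf_error("validation_error",
             sprintf("`%s` must be a non-empty numeric vector without NA", name))
  if (positive && any(x <= 0))
    sf_error("validation_error", sprintf("all values of `%s` must be > 0", name))
  invisible(x)
}

# strictly increasing check that reports the first offending index
check_strictly_increasing <- function(x, name) {
  bad <- which(diff(x) <= 0)
  if (length(bad))
    sf_error("validation_error",
             sprintf("`%s` must be strictly increasing (violated at row %d)",
                     name, bad[1] + 1L),
             row = bad[1] + 1L)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
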