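#' Time-indexed dynamic series
#'
#' The basic container for a voxel- or ROI-level curve: signal intensity,
#' longitudinal relaxation rate, or contrast-agent concentration sampled at
#' ordered time points. Each sample carries a validity flag; operations that
#' cannot produce a defined value (e.g. T1 estimation outside the domain of
#' the logarithm) mark samples invalid instead of emitting numbers, and
#' every downstream computation honours the flags.
#'
#' @param times Strictly increasing sampling instants.
#' @param values Measured or derived quantity per instant; `NA` entries are
#'   marked invalid automatically.
#' @param valid Optional logical vector of per-sample validity.
#' @param unit Unit of `values` as free text, e.g. `"a.u."`, `"1/s"`,
#'   `"mM"`, `"ms"`.
#' @param time_unit `"s"` (default) or `"min"`.
#' @return An object of class `dynamic_series`: a list with elements
#'   `times`, `values`, `valid`, `unit`, `time_unit`.
#' @examples
#' dynamic_series(times = c(0, 13.32, 26.64), values = c(0.8, 0.9, 1.0),
#'                unit = "1/s")
#' @export
dynamic_series <- function(times, values, valid = NULL, unit = "a.u.",
                           time_unit = c("s", "min")) {
  time_unit <- match.arg(time_unit)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  valid <- as.logical(valid)
  if (length(valid) != length(values))
    stop("valid must match the length of values", call. = FALSE)
  valid <- valid & is.finite(values)
  structure(
    list(times = times, values = values, valid = valid,
         unit = unit, time_unit = time_unit),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("dynamic series: %d samples [%s] over %g-%g %s (%d valid)\n",
              length(x$times), x$unit,
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA,
              x$time_unit, sum(x$valid)))
  invisible(x)
}

#' @export
length.dynamic_series <- function(x) length(x$times)

#' @export
as.data.frame.dynamic_series <- function(x, ...) {
  data.frame(time = x$times, value = x$values, valid = x$valid)
}

# Sampling instants converted to minutes (kinetic rate constants are per
# minute; relaxation stays per second).
times_min <- function(series) {
  if (series$time_unit == "min") series$times else series$times / 60
}

# Values with invalid samples replaced by NA, for safe numeric use.
valid_values <- function(series) {
  v <- series$values
  v[!series$valid] <- NA_real_
  v
}
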