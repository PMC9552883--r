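# Light-exposure time series: the stimulus container used throughout.

LIGHT_UNITS <- c("lux", "cla", "cs")

#' Construct a light-exposure time series
#'
#' A `light_series` holds a (possibly irregularly sampled) photic time
#' series: sample times in decimal hours since the series origin, the
#' light quantity at each sample, and a unit tag. Three units are
#' supported: `"lux"` (photopic illuminance), `"cla"` (circadian light,
#' CL_A, irradiance spectrally weighted for the circadian system) and
#' `"cs"` (circadian stimulus, the saturating transform of CL_A with
#' asymptote 0.7). The time origin is midnight, so `time %% 24` is local
#' clock time; wearable-logger storage intervals of 30-180 s are typical.
#'
#' Values must be nonnegative; small negative sensor noise is clamped to
#' zero with a warning. Out-of-order timestamps are sorted with a warning.
#' CS-unit values may not exceed the configured asymptote.
#'
#' @param time Numeric vector, hours since the series origin (midnight).
#' @param value Numeric vector of light readings, same length as `time`.
#' @param unit One of `"lux"`, `"cla"`, `"cs"`.
#' @param asymptote CS response ceiling used to validate `cs` values.
#' @return An object of class `light_series`: a data frame with columns
#'   `time` and `value` and a `unit` attribute.
#' @seealso [read_light_csv()], [prepare_drive_series()]
#' @export
light_series <- function(time, value, unit = c("lux", "cla", "cs"),
                         asymptote = 0.7) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(time), is.numeric(value),
            length(time) == length(value), length(time) >= 1L)
  if (anyNA(time) || anyNA(value) || any(!is.finite(time)))
    stop("light_series: times and values must be finite and non-missing")
  if (is.unsorted(time, strictly = FALSE)) {
    warning("light_series: timestamps out of order; sorting")
    o <- order(time)
    time <- time[o]
    value <- value[o]
  }
  if (any(value < 0)) {
    warning(sprintf(
      "light_series: %d negative reading(s) clamped to 0", sum(value < 0)))
    value[value < 0] <- 0
  }
  if (unit == "cs" && any(value > asymptote + 1e-9))
    stop(sprintf("light_series: cs values exceed the asymptote %.3g",
                 asymptote))
  out <- data.frame(time = as.numeric(time), value = as.numeric(value))
  attr(out, "unit") <- unit
  class(out) <- c("light_series", "data.frame")
  out
}

#' @export
print.light_series <- function(x, ...) {
  cat(sprintf("<light_series> %d samples, unit '%s', %.2f-%.2f h\n",
              nrow(x), light_unit(x), min(x$time), max(x$time)))
  if (nrow(x) > 1L)
    cat(sprintf("  median sampling interval: %.0f s\n",
                stats::median(diff(x$time)) * 3600))
  invisible(x)
}

#' Unit tag of a light series
#' @param x A `light_series`.
#' @return `"lux"`, `"cla"` or `"cs"`.
#' @export
light_unit <- function(x) attr(x, "unit")

#' Read and write light-series CSV files
#'
#' The on-disk dialect has a header `subject_id,timestamp,value,unit` with
#' ISO-8601 timestamps and unit tokens `lux`, `cla` or `cs`. On reading,
#' times are converted to decimal hours since midnight of the first
#' sample's day so that `time %% 24` is clock time; the round trip
#' preserves timestamps to 1 s and values to 1e-6. Malformed rows are
#' reported with their line numbers.
#'
#' @param path File path.
#' @param series A `light_series` to write.
#' @param subject_id Subject identifier written to the first column.
#' @param origin_date Calendar date (ISO) used for the written timestamps.
#' @return `read_light_csv()` returns a `light_series` (with the subject
#'   id in attribute `subject_id`); `write_light_csv()` returns `path`
#'   invisibly.
#' @export
read_light_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "value", "unit")
  if (!all(need %in% names(df)))
    stop("light CSV must have columns subject_id,timestamp,value,unit")
  ts <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(ts)
  ts[alt] <- as.POSIXct(strptime(df$timestamp[alt], "%Y-%m-%d %H:%M:%S",
                                 tz = "UTC"))
  bad <- which(is.na(ts) | is.na(suppressWarnings(as.numeric(df$value))))
  if (length(bad))
    stop(sprintf("malformed light CSV rows (data line%s %s) in %s",
                 if (length(bad) > 1) "s" else "", toString(bad), path))
  unit <- unique(tolower(df$unit))
  if (length(unit) != 1L || !unit %in% LIGHT_UNITS)
    stop(sprintf("unknown or mixed unit token(s): %s", toString(unique(df$unit))))
  day0 <- as.POSIXct(trunc(ts[1], units = "days"), tz = "UTC")
  hours <- as.numeric(difftime(ts, day0, units = "hours"))
  out <- light_series(hours, as.numeric(df$value), unit = unit)
  attr(out, "subject_id") <- df$subject_id[1]
  out
}

#' @rdname read_light_csv
#' @export
write_light_csv <- function(series, path, subject_id = "S1",
                            origin_date = "2000-01-01") {
  stopifnot(inherits(series, "light_series"))
  day0 <- as.POSIXct(paste(origin_date, "00:00:00"), tz = "UTC")
  ts <- day0 + round(series$time * 3600)
  df <- data.frame(
    subject_id = subject_id,
    timestamp = format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    value = sprintf("%.6f", series$value),
    unit = light_unit(series))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
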