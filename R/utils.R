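#' @importFrom data.table := .I .N .SD as.data.table data.table fread fwrite
#'   rbindlist setcolorder setorderv shift copy setDT setnames
#' @importFrom stats runif
#' @importFrom utils head
NULL

# Soft-deprecation shim for NULL defaults
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse character timestamps against an ordered list of candidate formats
#'
#' Thin wrapper around [lubridate::parse_date_time()] used by every reader in
#' the package, so detections and metadata share one parsing behaviour. Strings
#' are tried against `formats` in order; all results are normalised to UTC.
#' Any string that fails every candidate format is an error (never a silent
#' `NA`): spurious-detection filtering is meaningless if timestamps are wrong.
#'
#' @param x character vector of timestamp strings.
#' @param formats ordered character vector of `lubridate` order strings, e.g.
#'   `c("ymd HMS", "dmy HMS")`. Fractional seconds are supported via the `OS`
#'   order component (e.g. `"ymd HMOS"`).
#' @param tz time zone the strings are recorded in (default `"UTC"`). Parsed
#'   instants are converted to UTC.
#' @param context label used in error messages (e.g. a file name).
#' @return a `POSIXct` vector in UTC, same length as `x`.
#' @export
#' @examples
#' parse_timestamps("01/06/2021 12:00:00", "dmy HMS")
parse_timestamps <- function(x, formats, tz = "UTC", context = "timestamps") {
  x <- as.character(x)
  ts <- lubridate::parse_date_time(x, orders = formats, tz = tz, quiet = TRUE)
  bad <- which(is.na(ts))
  if (length(bad) > 0L) {
    shown <- head(bad, 5L)
    stop(sprintf(
      "%s: %d timestamp(s) failed all candidate formats [%s]; rows %s: %s",
      context, length(bad), paste(formats, collapse = ", "),
      paste(shown, collapse = ", "),
      paste(sprintf("'%s'", x[shown]), collapse = ", ")
    ), call. = FALSE)
  }
  if (!identical(tz, "UTC")) ts <- lubridate::with_tz(ts, "UTC")
  ts
}

# Format POSIXct the way every writer in the package serialises it.
# Sub-second digits are appended only when present, so second-resolution data
# round-trips byte-identically.
format_timestamp <- function(x) {
  out <- format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  frac <- as.numeric(x) - floor(as.numeric(x))
  has_frac <- !is.na(frac) & frac > 1e-9
  if (any(has_frac)) {
    out[has_frac] <- sub("0+$", "", format(x[has_frac], "%Y-%m-%d %H:%M:%OS6",
                                           tz = "UTC"))
  }
  out
}

# Stop unless `x` is a single finite number satisfying `ok`.
check_number <- function(x, name, ok = function(v) TRUE, what = "a number") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !ok(x)) {
    stop(sprintf("`%s` must be %s", name, what), call. = FALSE)
  }
  invisible(x)
}

# Require columns on a detection (or metadata) table, with a stage label.
check_columns <- function(x, cols, stage) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    stop(sprintf("%s: required column(s) missing from input: %s",
                 stage, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
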