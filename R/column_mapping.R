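#' Declare how raw receiver export files map onto the canonical detection table
#'
#' Receiver vendors export detection logs in slightly different delimited
#' layouts: different column names, preamble lines above the header, combined
#' or split date/time columns, different datetime formats. A `column_mapping`
#' declares all of this once, so file compilation is fully non-interactive and
#' reproducible.
#'
#' @param transmitter source column label holding transmitter IDs.
#' @param receiver source column label holding receiver IDs.
#' @param datetime source column label(s) holding the timestamp: length 1 for
#'   a combined date-time column, length 2 (`c(date, time)`) when date and
#'   time sit in separate columns, which are concatenated before parsing.
#' @param datetime_formats ordered character vector of candidate
#'   `lubridate` order strings tried in turn (e.g. `c("ymd HMS", "dmy HMS")`).
#' @param delimiter single field-separator character (default `","`).
#' @param header_row 1-based row index of the header line in the raw file, or
#'   `"none"` if the file has no header (then supply `column_names`).
#' @param skip_rows number of leading preamble rows to drop (the header row is
#'   dropped in addition to these).
#' @param drop_columns source column labels to discard entirely; all other
#'   non-consumed columns are retained as extras.
#' @param column_names optional character vector naming the columns when
#'   `header_row = "none"`.
#' @param tz time zone the file's timestamps are recorded in; instants are
#'   normalised to UTC on ingest.
#' @return an object of class `column_mapping`.
#' @export
#' @examples
#' column_mapping(
#'   transmitter = "Transmitter", receiver = "Receiver",
#'   datetime = "Date and Time (UTC)", datetime_formats = "ymd HMS"
#' )
column_mapping <- function(transmitter, receiver, datetime, datetime_formats,
                           delimiter = ",", header_row = 1L, skip_rows = 0L,
                           drop_columns = character(), column_names = NULL,
                           tz = "UTC") {
  stopifnot(is.character(transmitter), length(transmitter) == 1L,
            is.character(receiver), length(receiver) == 1L,
            is.character(datetime),
            is.character(datetime_formats), length(datetime_formats) >= 1L)
  if (!length(datetime) %in% 1:2) {
    stop("`datetime` must name one combined column or two split (date, time) columns",
         call. = FALSE)
  }
  if (identical(transmitter, receiver)) {
    stop("`transmitter` and `receiver` must be different source columns",
         call. = FALSE)
  }
  if (!is.character(delimiter) || length(delimiter) != 1L || nchar(delimiter) != 1L) {
    stop("`delimiter` must be a single character", call. = FALSE)
  }
  if (identical(header_row, "none")) {
    header_row <- "none"
  } else {
    check_number(header_row, "header_row", function(v) v >= 1 && v == floor(v),
                 "a positive row index or \"none\"")
    header_row <- as.integer(header_row)
  }
  check_number(skip_rows, "skip_rows", function(v) v >= 0 && v == floor(v),
               "a non-negative count")
  if (!identical(header_row, "none") && header_row <= skip_rows) {
    stop("`header_row` must lie after the skipped preamble rows", call. = FALSE)
  }
  structure(
    list(
      transmitter = transmitter, receiver = receiver,
      datetime = datetime,
      datetime_mode = if (length(datetime) == 1L) "combined" else "split",
      datetime_formats = datetime_formats,
      delimiter = delimiter, header_row = header_row,
      skip_rows = as.integer(skip_rows),
      drop_columns = as.character(drop_columns),
      column_names = column_names, tz = tz
    ),
    class = "column_mapping"
  )
}

#' @export
print.column_mapping <- function(x, ...) {
  cat("<column_mapping>\n")
  cat("  datetime   :", paste(x$datetime, collapse = " + "),
      sprintf("(%s; formats: %s; tz %s)\n", x$datetime_mode,
              paste(x$datetime_formats, collapse = ", "), x$tz))
  cat("  transmitter:", x$transmitter, "\n")
  cat("  receiver   :", x$receiver, "\n")
  cat("  layout     : delimiter '", x$delimiter, "', header row ",
      as.character(x$header_row), ", skip ", x$skip_rows, " row(s)\n", sep = "")
  invisible(x)
}
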