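#' Find raw detection files in a folder
#'
#' Matches on file extension, case-insensitively (vendors export both `.csv`
#' and `.CSV`), and returns paths sorted lexicographically so the compile
#' order — and therefore which copy of a duplicated detection survives — is
#' deterministic.
#'
#' @param folder directory to scan (not recursive).
#' @param extension file extension including the dot, default `".csv"`.
#' @return character vector of full paths, lexicographically sorted.
#' @export
scan_detection_files <- function(folder, extension = ".csv") {
  if (!dir.exists(folder)) {
    stop(sprintf("detection folder does not exist: %s", folder), call. = FALSE)
  }
  files <- list.files(folder, full.names = TRUE)
  files <- files[!dir.exists(files)]
  hit <- endsWith(tolower(basename(files)), tolower(extension))
  files <- sort(files[hit], method = "radix")
  if (length(files) == 0L) {
    stop(sprintf("no detection files found in '%s' with extension '%s'",
                 folder, extension), call. = FALSE)
  }
  files
}

#' Parse one raw detection file into the canonical detection layout
#'
#' Applies a [column_mapping()]: drops preamble rows, reads the header (or
#' applies supplied names), concatenates split date/time columns, parses
#' timestamps (error — never a silent drop — when a timestamp fails every
#' candidate format), and returns one row per source row, in source order.
#' Source columns that are not consumed by the mapping and not listed in
#' `drop_columns` are retained unchanged ("extras").
#'
#' @param path file to read.
#' @param mapping a [column_mapping()].
#' @return a `data.table` with columns `timestamp` (POSIXct, UTC),
#'   `transmitter`, `receiver`, `source_file`, then any retained extras.
#' @export
parse_detection_file <- function(path, mapping) {
  stopifnot(inherits(mapping, "column_mapping"))
  if (!file.exists(path)) stop(sprintf("cannot read file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]

  drop_idx <- seq_len(mapping$skip_rows)
  if (identical(mapping$header_row, "none")) {
    col_names <- mapping$column_names
  } else {
    if (mapping$header_row > length(lines)) {
      stop(sprintf("%s: header row %d beyond end of file", path,
                   mapping$header_row), call. = FALSE)
    }
    col_names <- as.character(fread(text = lines[mapping$header_row],
                                    sep = mapping$delimiter, header = FALSE)[1L, ])
    drop_idx <- union(drop_idx, mapping$header_row)
  }
  data_lines <- lines[setdiff(seq_along(lines), drop_idx)]
  if (length(data_lines) == 0L) {
    stop(sprintf("%s: no data rows after removing preamble/header", path),
         call. = FALSE)
  }
  dt <- fread(text = data_lines, sep = mapping$delimiter, header = FALSE,
              colClasses = "character", strip.white = TRUE)
  if (!is.null(col_names)) {
    if (length(col_names) != ncol(dt)) {
      stop(sprintf("%s: %d column names for %d columns", path,
                   length(col_names), ncol(dt)), call. = FALSE)
    }
    setnames(dt, col_names)
  }

  needed <- c(mapping$datetime, mapping$transmitter, mapping$receiver)
  check_columns(dt, needed, basename(path))

  raw_ts <- if (mapping$datetime_mode == "combined") {
    dt[[mapping$datetime]]
  } else {
    paste(dt[[mapping$datetime[1L]]], dt[[mapping$datetime[2L]]])
  }
  ts <- parse_timestamps(raw_ts, mapping$datetime_formats, tz = mapping$tz,
                         context = basename(path))

  transmitter <- as.character(dt[[mapping$transmitter]])
  receiver <- as.character(dt[[mapping$receiver]])
  empty <- which(!nzchar(transmitter) | !nzchar(receiver) |
                   is.na(transmitter) | is.na(receiver))
  if (length(empty) > 0L) {
    stop(sprintf("%s: empty transmitter/receiver ID in data row(s) %s",
                 basename(path), paste(head(empty, 5L), collapse = ", ")),
         call. = FALSE)
  }

  consumed <- unique(c(mapping$datetime, mapping$transmitter, mapping$receiver,
                       mapping$drop_columns))
  extras <- dt[, setdiff(names(dt), consumed), with = FALSE]
  clash <- intersect(names(extras), c("timestamp", "transmitter", "receiver",
                                      "source_file"))
  if (length(clash) > 0L) setnames(extras, clash, paste0("extra_", clash))

  out <- data.table(timestamp = ts, transmitter = transmitter,
                    receiver = receiver, source_file = basename(path))
  if (ncol(extras) > 0L) out <- cbind(out, extras)
  out[]
}

#' Split a detection table into unique rows and exact duplicates
#'
#' A duplicate is a repeated `(transmitter, receiver, timestamp)` key — the
#' same transmitter logged on the same receiver at the same instant, as
#' happens when overlapping receiver downloads are compiled together.
#' Sub-second timestamp fractions, when present, participate in the key. The
#' first occurrence in compile order survives; the other `k - 1` rows of a
#' size-`k` group go to the duplicates table.
#'
#' @param detections canonical detection table.
#' @return `list(unique = , duplicates = )`, both in input row order;
#'   `nrow(unique) + nrow(duplicates) == nrow(detections)`.
#' @export
partition_duplicates <- function(detections) {
  det <- as.data.table(detections)
  check_columns(det, c("timestamp", "transmitter", "receiver"), "partition_duplicates")
  dup <- duplicated(det, by = c("transmitter", "receiver", "timestamp"))
  list(unique = det[!dup], duplicates = det[dup])
}

#' Compile a folder of raw detection files into one detection table
#'
#' Scans `folder`, parses every matching file with the shared
#' [column_mapping()], concatenates (optionally in batches — batching is a
#' memory tactic only and provably does not change the result), partitions
#' exact duplicates, and sorts by `(timestamp, transmitter, receiver)`.
#'
#' @param folder directory containing the raw files.
#' @param mapping a [column_mapping()] shared by all files.
#' @param extension file extension to match (default `".csv"`).
#' @param batch_size number of files read per batch; `NULL` (default) reads
#'   all at once. The compiled output is identical for any batch size.
#' @param dedupe partition exact duplicates out (default `TRUE`).
#' @return `list(detections = , duplicates = , report = )` where `report` is a
#'   named count vector with `input = kept + duplicates`.
#' @export
compile_detections <- function(folder, mapping, extension = ".csv",
                               batch_size = NULL, dedupe = TRUE) {
  files <- scan_detection_files(folder, extension)
  if (is.null(batch_size)) batch_size <- length(files)
  check_number(batch_size, "batch_size", function(v) v >= 1 && v == floor(v),
               "a positive count")
  batches <- split(files, ceiling(seq_along(files) / batch_size))
  parts <- lapply(batches, function(fs) {
    rbindlist(lapply(fs, parse_detection_file, mapping = mapping),
              use.names = TRUE, fill = TRUE)
  })
  all_rows <- rbindlist(parts, use.names = TRUE, fill = TRUE)
  n_input <- nrow(all_rows)

  if (isTRUE(dedupe)) {
    p <- partition_duplicates(all_rows)
    det <- p$unique
    dups <- p$duplicates
  } else {
    det <- all_rows
    dups <- all_rows[0L]
  }
  setorderv(det, c("timestamp", "transmitter", "receiver"))
  list(
    detections = det,
    duplicates = dups,
    report = c(input = n_input, kept = nrow(det), duplicates = nrow(dups))
  )
}
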