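# Readers/validators for the three metadata tables every study carries:
# stations (where receivers sit), deployments (when each receiver sat there)
# and animals (which transmitter is in which animal from when). Each accepts a
# data.frame or a delimited-file path plus the user's source column labels, and
# returns a validated table with canonical column names, so the rest of the
# pipeline never sees user-specific headers.

read_meta <- function(x, delimiter) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(sprintf("cannot read file: %s", x), call. = FALSE)
    fread(x, sep = delimiter, colClasses = "character")
  } else {
    as.data.table(x)
  }
}

pick_cols <- function(dt, mapping, what) {
  check_columns(dt, unlist(mapping, use.names = FALSE), what)
  out <- dt[, unlist(mapping, use.names = FALSE), with = FALSE]
  setnames(out, names(mapping))
  out
}

#' Validate a station (spatial) table
#'
#' One row per station: the fixed geographic location where receivers are
#' (re)deployed. Coordinates are decimal degrees (WGS84); the optional range
#' category links stations to entries of a detection-range table used by the
#' speed filter.
#'
#' @param x data.frame or path to a delimited file.
#' @param station,latitude,longitude,range_category source column labels
#'   (`range_category = NULL` if absent).
#' @param delimiter field separator when `x` is a path.
#' @return a `data.table` with columns `station`, `latitude`, `longitude` and,
#'   if mapped, `range_category`.
#' @export
as_station_table <- function(x, station = "station", latitude = "latitude",
                             longitude = "longitude", range_category = NULL,
                             delimiter = ",") {
  dt <- read_meta(x, delimiter)
  mapping <- list(station = station, latitude = latitude, longitude = longitude)
  if (!is.null(range_category)) mapping$range_category <- range_category
  out <- pick_cols(dt, mapping, "station table")
  out[, `:=`(station = as.character(station),
             latitude = as.numeric(latitude),
             longitude = as.numeric(longitude))]
  if (anyDuplicated(out$station)) {
    stop(sprintf("station names are not unique: %s",
                 paste(unique(out$station[duplicated(out$station)]),
                       collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(out$latitude)) || any(abs(out$latitude) > 90) ||
      any(is.na(out$longitude)) || any(abs(out$longitude) > 180)) {
    stop("station coordinates must satisfy |latitude| <= 90 and |longitude| <= 180",
         call. = FALSE)
  }
  out[]
}

#' Validate a receiver-deployment table
#'
#' One row per deployment event: a receiver's residence at one station from
#' deployment to retrieval. Windows are closed at both ends; for any receiver
#' the windows must be pairwise non-overlapping, otherwise a detection could
#' be attributed to two stations at once and the function stops.
#'
#' @param x data.frame or path to a delimited file.
#' @param receiver,station,start,end source column labels.
#' @param datetime_formats candidate `lubridate` order strings for the
#'   deploy/retrieve timestamps.
#' @param tz time zone of the timestamps (normalised to UTC).
#' @param delimiter field separator when `x` is a path.
#' @return a `data.table` with columns `receiver`, `station`, `start`, `end`.
#' @export
as_deployment_table <- function(x, receiver = "receiver", station = "station",
                                start = "start", end = "end",
                                datetime_formats = "ymd HMS", tz = "UTC",
                                delimiter = ",") {
  dt <- read_meta(x, delimiter)
  out <- pick_cols(dt, list(receiver = receiver, station = station,
                            start = start, end = end), "deployment table")
  out[, `:=`(receiver = as.character(receiver), station = as.character(station))]
  out[, start := parse_timestamps(start, datetime_formats, tz, "deployment start")]
  out[, end := parse_timestamps(end, datetime_formats, tz, "deployment end")]
  if (any(out$start >= out$end)) {
    stop("every deployment must start before it ends", call. = FALSE)
  }
  check_no_overlap(out)
  out[]
}

# Closed intervals overlap iff, after sorting by start within receiver, a
# window starts at or before the previous one ends.
check_no_overlap <- function(dep) {
  d <- copy(dep)
  setorderv(d, c("receiver", "start"))
  bad <- d[, .(overlap = any(shift(end)[-1] >= start[-1])), by = receiver][
    overlap == TRUE, receiver]
  if (length(bad) > 0L) {
    stop(sprintf("overlapping deployment windows for receiver(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(dep)
}

#' Validate an animal (tagging) table
#'
#' One row per tag-implantation event, binding a transmitter to an animal from
#' the tagging time onward. Transmitters may be reused across animals
#' consecutively; `(transmitter, tagged_at)` pairs must be unique so the
#' latest-tagging-not-after-detection rule resolves unambiguously. All
#' unmapped source columns (biometrics such as body length, capture data, ...)
#' are retained and can be carried onto detections.
#'
#' @param x data.frame or path to a delimited file.
#' @param transmitter,animal,tagged_at source column labels.
#' @param tag_status,capture_station optional source column labels.
#' @param datetime_formats candidate `lubridate` order strings for tagging times.
#' @param tz time zone of the timestamps (normalised to UTC).
#' @param delimiter field separator when `x` is a path.
#' @return a `data.table` with canonical columns plus retained extras.
#' @export
as_animal_table <- function(x, transmitter = "transmitter", animal = "animal",
                            tagged_at = "tagged_at", tag_status = NULL,
                            capture_station = NULL,
                            datetime_formats = "ymd HMS", tz = "UTC",
                            delimiter = ",") {
  dt <- read_meta(x, delimiter)
  mapping <- list(transmitter = transmitter, animal = animal,
                  tagged_at = tagged_at)
  if (!is.null(tag_status)) mapping$tag_status <- tag_status
  if (!is.null(capture_station)) mapping$capture_station <- capture_station
  out <- pick_cols(dt, mapping, "animal table")
  extras <- dt[, setdiff(names(dt), unlist(mapping, use.names = FALSE)),
               with = FALSE]
  if (ncol(extras) > 0L) out <- cbind(out, extras)
  out[, `:=`(transmitter = as.character(transmitter),
             animal = as.character(animal))]
  out[, tagged_at := parse_timestamps(tagged_at, datetime_formats, tz,
                                      "animal tagging time")]
  if (anyDuplicated(out, by = c("transmitter", "tagged_at"))) {
    stop("(transmitter, tagged_at) pairs must be unique in the animal table",
         call. = FALSE)
  }
  out[]
}
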