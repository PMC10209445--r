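#' Attribute station metadata to detections via deployment windows
#'
#' A detection on receiver `r` at time `t` belongs to the unique deployment of
#' `r` whose closed window `[start, end]` contains `t`; it inherits that
#' deployment's station and the station's coordinates (and range category, if
#' present). Detections matching no window — logged while the receiver was on
#' land, in transit, or between deployments — are partitioned out, not
#' dropped.
#'
#' @param detections canonical detection table (from [compile_detections()]).
#' @param deployments validated deployment table ([as_deployment_table()]).
#' @param spatial validated station table ([as_station_table()]).
#' @return `list(attributed = , out_of_deployment = )`; rows keep their input
#'   order and `nrow(attributed) + nrow(out_of_deployment) == nrow(detections)`.
#' @export
attribute_stations <- function(detections, deployments, spatial) {
  det <- as.data.table(detections)
  dep <- as.data.table(deployments)
  spa <- as.data.table(spatial)
  check_columns(det, c("timestamp", "receiver"), "attribute_stations")
  check_columns(dep, c("receiver", "station", "start", "end"), "attribute_stations")
  check_columns(spa, c("station", "latitude", "longitude"), "attribute_stations")

  unknown_station <- setdiff(dep$station, spa$station)
  if (length(unknown_station) > 0L) {
    stop(sprintf("deployment table references station(s) absent from the spatial table: %s",
                 paste(unknown_station, collapse = ", ")), call. = FALSE)
  }
  check_no_overlap(dep)

  det <- copy(det)
  det[, .row__ := .I]
  hit <- dep[det, on = .(receiver, start <= timestamp, end >= timestamp),
             .(.row__ = i..row__, station = x.station)]
  # windows are non-overlapping, so each detection matched at most once
  det[hit, on = ".row__", station := i.station]

  matched <- !is.na(det$station)
  attributed <- det[matched]
  out <- det[!matched]
  out[, station := NULL]

  spa_cols <- intersect(c("latitude", "longitude", "range_category"), names(spa))
  attributed <- merge(attributed, spa[, c("station", spa_cols), with = FALSE],
                      by = "station", all.x = TRUE, sort = FALSE)
  setorderv(attributed, ".row__")
  setcolorder(attributed, c(setdiff(names(attributed),
                                    c("station", spa_cols, ".row__")),
                            "station", spa_cols))
  attributed[, .row__ := NULL]
  out[, .row__ := NULL]
  list(attributed = attributed[], out_of_deployment = out[])
}

#' Attribute animal identities to detections via tagging history
#'
#' A detection of transmitter `x` at time `t` maps to the animal whose tagging
#' time is the latest `tagged_at <= t` among records sharing `x` — this is
#' what lets one transmitter be deployed consecutively in several animals.
#' Detections with no qualifying record (a transmitter absent from the animal
#' table, or detected before its first tagging) are partitioned into the
#' unknown-tag table, as are detections within the first `discard_first` hours
#' after the matched tagging event (post-tagging behaviour is not
#' representative, so many studies discard it).
#'
#' @param detections detection table (normally station-attributed).
#' @param animals validated animal table ([as_animal_table()]).
#' @param discard_first hours after each tagging event to discard (default 0).
#'   Applies per tagging event, so a retagged animal gets a fresh window.
#' @param carry animal-table columns to copy onto attributed detections, in
#'   addition to `animal`; default: every non-key animal column.
#' @return `list(attributed = , unknown = )`; rows keep their input order and
#'   the two parts partition the input exactly.
#' @export
attribute_animals <- function(detections, animals, discard_first = 0,
                              carry = NULL) {
  det <- as.data.table(detections)
  ani <- as.data.table(animals)
  check_columns(det, c("timestamp", "transmitter"), "attribute_animals")
  check_columns(ani, c("transmitter", "animal", "tagged_at"), "attribute_animals")
  check_number(discard_first, "discard_first", function(v) v >= 0,
               "a non-negative number of hours")
  if (is.null(carry)) {
    carry <- setdiff(names(ani), c("transmitter", "tagged_at"))
  } else {
    carry <- union("animal", carry)
    check_columns(ani, carry, "attribute_animals")
  }

  det <- copy(det)
  det[, .row__ := .I]
  if (nrow(ani) == 0L) {
    unknown <- det
    unknown[, .row__ := NULL]
    return(list(attributed = unknown[0L], unknown = unknown[]))
  }

  lookup <- copy(ani)
  lookup[, .join_time__ := tagged_at]
  probe <- det[, .(transmitter, .join_time__ = timestamp, .row__)]
  # roll = Inf: latest tagging time at or before the detection
  m <- lookup[probe, on = .(transmitter, .join_time__), roll = Inf,
              c(".row__", "tagged_at", carry), with = FALSE]

  m[, .keep__ := !is.na(tagged_at) &
      det$timestamp[.row__] >= tagged_at + discard_first * 3600]
  det[m, on = ".row__", `:=`(.keep__ = i..keep__)]
  det[m, on = ".row__", (carry) := mget(paste0("i.", carry))]

  attributed <- det[.keep__ == TRUE]
  unknown <- det[.keep__ != TRUE]
  drop_cols <- intersect(carry, names(unknown))
  if (length(drop_cols) > 0L) unknown[, (drop_cols) := NULL]
  attributed[, c(".row__", ".keep__") := NULL]
  unknown[, c(".row__", ".keep__") := NULL]
  list(attributed = attributed[], unknown = unknown[])
}
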