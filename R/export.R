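# Split a transmitter ID like "A69-1602-12345" into code space and signal.
split_transmitter <- function(transmitter, what) {
  signal <- sub(".*-", "", transmitter)
  codespace <- sub("-[0-9]+$", "", transmitter)
  if (any(!grepl("^[0-9]+$", signal))) {
    bad <- transmitter[!grepl("^[0-9]+$", signal)]
    stop(sprintf(
      "%s: cannot derive a numeric Signal from transmitter ID(s): %s",
      what, paste(unique(head(bad, 5L)), collapse = ", ")), call. = FALSE)
  }
  list(codespace = codespace, signal = as.integer(signal))
}

write_atomic <- function(dt, path) {
  tmp <- paste0(path, ".tmp")
  fwrite(dt, tmp)
  file.rename(tmp, path)
  path
}

#' Export the filtered dataset in the layout used by downstream analysis
#'
#' Writes four cross-consistent files to `target_folder`: `detections.csv`
#' (one row per kept detection: `Timestamp`, `Receiver`, `CodeSpace`,
#' `Signal`, `Station`), `biometrics.csv` (`Release.date`, `Signal`, `Group`,
#' plus any extra animal columns), `deployments.csv` (`Receiver`,
#' `Station.name`, `Start`, `Stop`) and `spatial.csv` (`Station.name`,
#' `Latitude`, `Longitude`, `Array`, `Type`). Transmitter IDs must end in a
#' numeric signal (`<code space>-<signal>`, the usual vendor form).
#' Timestamps are serialised as `YYYY-mm-dd HH:MM:SS`. Files are written via
#' temporary names and renamed into place, and the export is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param detections kept detection table (after filtering) with `timestamp`,
#'   `transmitter`, `receiver`, `station` columns.
#' @param animals validated animal table.
#' @param deployments validated deployment table.
#' @param spatial validated station table.
#' @param target_folder output directory (created if needed).
#' @return invisibly, a named list of the four file paths.
#' @export
export_actel <- function(detections, animals, deployments, spatial,
                         target_folder) {
  det <- as.data.table(detections)
  ani <- as.data.table(animals)
  dep <- as.data.table(deployments)
  spa <- as.data.table(spatial)
  check_columns(det, c("timestamp", "transmitter", "receiver", "station"),
                "export detections")
  check_columns(ani, c("transmitter", "animal", "tagged_at"), "export biometrics")
  check_columns(dep, c("receiver", "station", "start", "end"), "export deployments")
  check_columns(spa, c("station", "latitude", "longitude"), "export spatial")
  ref <- setdiff(dep$station, spa$station)
  if (length(ref) > 0L) {
    stop(sprintf("deployments reference station(s) missing from spatial: %s",
                 paste(ref, collapse = ", ")), call. = FALSE)
  }
  dir.create(target_folder, showWarnings = FALSE, recursive = TRUE)

  dtx <- split_transmitter(det$transmitter, "export detections")
  detections_out <- data.table(
    Timestamp = format_timestamp(det$timestamp),
    Receiver = det$receiver,
    CodeSpace = dtx$codespace,
    Signal = dtx$signal,
    Station = det$station
  )

  atx <- split_transmitter(ani$transmitter, "export biometrics")
  biometrics_out <- data.table(
    Release.date = format_timestamp(ani$tagged_at),
    Signal = atx$signal,
    Group = if ("tag_status" %in% names(ani)) ani$tag_status else "A"
  )
  extra <- setdiff(names(ani), c("transmitter", "tagged_at", "tag_status"))
  if (length(extra) > 0L) {
    biometrics_out <- cbind(biometrics_out, ani[, extra, with = FALSE])
  }

  deployments_out <- data.table(
    Receiver = dep$receiver,
    Station.name = dep$station,
    Start = format_timestamp(dep$start),
    Stop = format_timestamp(dep$end)
  )
  spatial_out <- data.table(
    Station.name = spa$station,
    Latitude = spa$latitude,
    Longitude = spa$longitude,
    Array = "A1",
    Type = "Hydrophone"
  )

  paths <- list(
    detections_file = write_atomic(detections_out,
                                   file.path(target_folder, "detections.csv")),
    biometrics_file = write_atomic(biometrics_out,
                                   file.path(target_folder, "biometrics.csv")),
    deployments_file = write_atomic(deployments_out,
                                    file.path(target_folder, "deployments.csv")),
    spatial_file = write_atomic(spatial_out,
                                file.path(target_folder, "spatial.csv"))
  )
  invisible(structure(paths, class = "actel_bundle"))
}
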