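library(data.table)

utc <- function(x) as.POSIXct(x, tz = "UTC")

# Minimal canonical detection table builder.
det_table <- function(timestamp, transmitter = "A69-1602-1001",
                      receiver = "R01", animal = "F01", station = "S01", ...) {
  data.table(timestamp = timestamp, transmitter = transmitter,
             receiver = receiver, animal = animal, station = station, ...)
}

# Independent O(n^2) solitary oracle: a detection is solitary iff no OTHER
# detection in its group lies strictly within `delay` hours of it. All n^2
# pairwise gaps are scanned; no sorting, no neighbour shortcuts.
brute_solitary <- function(det, delay, per_receiver) {
  det <- as.data.table(det)
  key <- if (per_receiver) paste(det$animal, det$receiver, sep = "\r")
         else det$animal
  tt <- as.numeric(det$timestamp)
  n <- nrow(det)
  close_pair <- abs(outer(tt, tt, "-")) < delay * 3600 &
    outer(key, key, "==")
  diag(close_pair) <- FALSE
  rowSums(close_pair) == 0
}

# Independent audit of speed-filter output: scan kept rows per animal in time
# order (receiver tie-break) and count consecutive-pair violations.
count_speed_violations <- function(kept, dist_matrix, speed_mh_by_animal,
                                   range_m, max_distance = NULL) {
  k <- as.data.table(kept)
  tie <- intersect(c("receiver", "station"), names(k))[1L]
  setorderv(k, c("animal", "timestamp", tie))
  bad <- 0L
  for (a in unique(k$animal)) {
    s <- k[animal == a]
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1L)) {
      d <- dist_matrix[s$station[i], s$station[i + 1L]]
      eff <- max(0, d - 2 * range_m)
      dt_h <- as.numeric(s$timestamp[i + 1L] - s$timestamp[i], units = "hours")
      req <- if (eff == 0) 0 else if (dt_h == 0) Inf else eff / dt_h
      viol <- req > speed_mh_by_animal[[a]]
      if (!is.null(max_distance)) viol <- viol || d > max_distance
      if (viol) bad <- bad + 1L
    }
  }
  bad
}

# Write a small raw detection file from a data.frame of character columns.
write_raw_lines <- function(path, header, rows, preamble = character()) {
  writeLines(c(preamble, header, rows), path)
  path
}

# Generate a fixture and run the full pipeline with the parameters the
# fixture was designed around.
run_fixture_pipeline <- function(cfg, dir, per_receiver = TRUE, ...) {
  fix <- simulate_telemetry(cfg, dir)
  dep <- as_deployment_table(file.path(fix$dir, "deployments.csv"))
  spa <- as_station_table(file.path(fix$dir, "spatial.csv"),
                          range_category = "range_category")
  ani <- as_animal_table(file.path(fix$dir, "animals.csv"))
  res <- run_pipeline(
    fix$detections_dir, fixture_mapping(cfg), dep, spa, ani,
    delay = cfg$delay_hours, per_receiver = per_receiver,
    model = speed_model(cfg$speed_base, "length_mm", cfg$speed_exponent),
    ranges = range_spec(cfg$receiver_range_m), ...
  )
  list(fix = fix, res = res, spatial = spa, deployments = dep, animals = ani)
}

# Map truth bins onto pipeline result tables.
bin_of <- function(res, lbl) {
  switch(lbl,
         genuine = res$kept,
         duplicate = res$bins$duplicates,
         out_of_window = res$bins$out_of_deployment,
         unknown_tag = res$bins$unknown_tag,
         solitary = res$bins$solitary,
         speed = res$bins$speed)
}
truth_bins <- c("genuine", "duplicate", "out_of_window", "unknown_tag",
                "solitary", "speed")
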