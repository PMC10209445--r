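#' Configure the synthetic telemetry study generator
#'
#' Defines the conditions of a simulated passive-telemetry study: a line of
#' stations with one receiver each (each receiver serviced once mid-study,
#' giving every receiver two deployment windows separated by an on-land gap),
#' tagged animals moving between adjacent stations in residency bouts of 3-8
#' detections, and planted contamination of five kinds, each violating
#' exactly one pipeline rule so its destination bin is unambiguous:
#' exact duplicate rows (re-downloaded data), rows logged during the service
#' gap, rows from transmitters absent from the animal table, solitary ghosts
#' (isolated by at least twice the solitary delay from any same-animal
#' detection), and teleport ghosts (placed minutes after a genuine detection
#' at a station whose effective distance cannot be crossed that fast, with a
#' feasible onward leg to the animal's next genuine bout at the same station).
#'
#' @param n_animals,n_stations,study_days study dimensions (defaults 4, 3, 14).
#' @param detection_rate genuine detections per animal-hour (default 1.2).
#' @param n_duplicates,n_out_of_window,n_unknown_tag,n_solitary_ghosts,n_teleport_ghosts
#'   planted rows per contamination class (defaults 10).
#' @param delay_hours solitary-rule delay the study is designed around
#'   (default 1 h, the per-receiver convention of the field).
#' @param receiver_range_m detection range of every receiver (default 250 m).
#' @param station_spacing_m distance between adjacent stations (default 4000 m).
#' @param speed_base,speed_exponent allometric maximum-speed law
#'   `base * TL^exponent` in m/s on total length in mm (defaults 0.019, 0.75,
#'   the critical-swimming-speed law for fish).
#' @param length_range_mm animal total-length range (default 450-700 mm).
#' @param split_datetime write separate `Date`/`Time` columns (dd/mm/YYYY)
#'   instead of one combined column.
#' @param preamble_rows non-data preamble lines atop each raw file.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return an object of class `fixture_config`.
#' @export
fixture_config <- function(n_animals = 4L, n_stations = 3L, study_days = 14,
                           detection_rate = 1.2,
                           n_duplicates = 10L, n_out_of_window = 10L,
                           n_unknown_tag = 10L, n_solitary_ghosts = 10L,
                           n_teleport_ghosts = 10L,
                           delay_hours = 1, receiver_range_m = 250,
                           station_spacing_m = 4000,
                           speed_base = 0.019, speed_exponent = 0.75,
                           length_range_mm = c(450, 700),
                           split_datetime = FALSE, preamble_rows = 0L,
                           seed = 1L) {
  counts <- c(n_duplicates = n_duplicates, n_out_of_window = n_out_of_window,
              n_unknown_tag = n_unknown_tag,
              n_solitary_ghosts = n_solitary_ghosts,
              n_teleport_ghosts = n_teleport_ghosts)
  if (any(counts < 0)) stop("planted counts must be >= 0", call. = FALSE)
  check_number(n_animals, "n_animals", function(v) v >= 1)
  check_number(n_stations, "n_stations", function(v) v >= 1)
  check_number(study_days, "study_days", function(v) v >= 2)
  check_number(detection_rate, "detection_rate", function(v) v > 0)
  check_number(delay_hours, "delay_hours", function(v) v > 0)
  if (n_teleport_ghosts > 0 && n_stations < 2) {
    stop("teleport ghosts need at least 2 stations", call. = FALSE)
  }
  if (n_teleport_ghosts > 0 &&
      station_spacing_m <= 2 * receiver_range_m + 500) {
    stop("teleport ghosts need station spacing well beyond twice the receiver range",
         call. = FALSE)
  }
  structure(
    list(n_animals = as.integer(n_animals), n_stations = as.integer(n_stations),
         study_days = study_days, detection_rate = detection_rate,
         n_duplicates = as.integer(n_duplicates),
         n_out_of_window = as.integer(n_out_of_window),
         n_unknown_tag = as.integer(n_unknown_tag),
         n_solitary_ghosts = as.integer(n_solitary_ghosts),
         n_teleport_ghosts = as.integer(n_teleport_ghosts),
         delay_hours = delay_hours, receiver_range_m = receiver_range_m,
         station_spacing_m = station_spacing_m,
         speed_base = speed_base, speed_exponent = speed_exponent,
         length_range_mm = length_range_mm,
         split_datetime = isTRUE(split_datetime),
         preamble_rows = as.integer(preamble_rows), seed = as.integer(seed)),
    class = "fixture_config"
  )
}

#' Column mapping matching the raw files a fixture writes
#'
#' @param config the [fixture_config()] the files were generated from.
#' @return a [column_mapping()] suitable for [compile_detections()].
#' @export
fixture_mapping <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  if (config$split_datetime) {
    column_mapping(transmitter = "Transmitter", receiver = "Receiver",
                   datetime = c("Date", "Time"), datetime_formats = "dmy HMS",
                   header_row = config$preamble_rows + 1L,
                   skip_rows = config$preamble_rows)
  } else {
    column_mapping(transmitter = "Transmitter", receiver = "Receiver",
                   datetime = "DateTime", datetime_formats = "ymd HMS",
                   header_row = config$preamble_rows + 1L,
                   skip_rows = config$preamble_rows)
  }
}

# Round-robin split of n planted events over k animals.
spread_counts <- function(n, k) {
  tabulate(rep(seq_len(k), length.out = n), nbins = k)
}

#' Generate a seeded, ground-truth-labelled synthetic telemetry dataset
#'
#' Writes raw per-receiver detection files (plus a re-download file carrying
#' the duplicate copies), the three metadata files (`spatial.csv`,
#' `deployments.csv`, `animals.csv`), a station distance matrix
#' (`distance_matrix.csv`) and a `truth.csv` labelling every emitted data row
#' with its intended pipeline bin (`genuine`, `duplicate`, `out_of_window`,
#' `unknown_tag`, `solitary`, `speed`). Duplicate copies share the `uid` of
#' the row they duplicate.
#'
#' Raw detection files are written to a `detections/` subfolder of `dir`;
#' metadata, the distance matrix and `truth.csv` sit in `dir` itself.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, `list(dir, detections_dir, files, truth, config)`.
#' @export
simulate_telemetry <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  det_dir <- file.path(dir, "detections")   # raw exports live apart from metadata
  dir.create(det_dir, showWarnings = FALSE, recursive = TRUE)

  t0 <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC")
  day <- 86400
  study_end <- t0 + config$study_days * day
  svc0 <- t0 + 0.45 * config$study_days * day  # receivers lifted for service
  svc1 <- t0 + 0.55 * config$study_days * day

  # --- stations along a meridian: adjacent arc distance is exact ------------
  ns <- config$n_stations
  lat_step <- config$station_spacing_m / (pi / 180 * 6371000)
  stations <- data.table(
    station = sprintf("S%02d", seq_len(ns)),
    latitude = 54.40 + (seq_len(ns) - 1L) * lat_step,
    longitude = 13.60,
    range_category = "std"
  )
  receivers <- sprintf("R%02d", seq_len(ns))   # one receiver per station
  deployments <- rbindlist(lapply(seq_len(ns), function(i) {
    data.table(receiver = receivers[i], station = stations$station[i],
               start = c(t0 - 12 * 3600, svc1),
               end = c(svc0, study_end + 12 * 3600))
  }))

  # --- animals --------------------------------------------------------------
  na <- config$n_animals
  animals <- data.table(
    animal = sprintf("F%02d", seq_len(na)),
    transmitter = sprintf("A69-1602-%d", 1000L + seq_len(na)),
    tagged_at = t0 - 2 * day,
    tag_status = "tagged",
    capture_station = stations$station[sample.int(ns, na, replace = TRUE)],
    length_mm = round(runif(na, config$length_range_mm[1], config$length_range_mm[2]))
  )
  speeds_mh <- config$speed_base * animals$length_mm^config$speed_exponent * 3600

  delay <- config$delay_hours
  eff_adj <- max(config$station_spacing_m - 2 * config$receiver_range_m, 0)
  max_eff <- max((ns - 1) * config$station_spacing_m - 2 * config$receiver_range_m, 0)

  n_tel <- spread_counts(config$n_teleport_ghosts, na)
  n_sol <- spread_counts(config$n_solitary_ghosts, na)

  # a teleport ghost 1-3 min after a detection one station away must exceed
  # every animal's maximum speed, or it could never be flagged
  if (config$n_teleport_ghosts > 0 && any(speeds_mh >= eff_adj / (3 / 60))) {
    stop("infeasible config: animals are fast enough to make the planted teleport arrivals feasible",
         call. = FALSE)
  }

  study_hours <- config$study_days * 24
  n_bouts_target <- max(ceiling(config$detection_rate * study_hours / 5.5), 8)
  mean_gap_h <- max(study_hours / n_bouts_target - 0.5, 1.2)

  rows <- list()
  for (a in seq_len(na)) {
    travel_h <- eff_adj / speeds_mh[a]
    gap_floor <- max(1.15 * travel_h, 0.25)
    lo_t <- max(1.25 * travel_h, 0.55 * delay)
    hi_t <- 0.92 * delay
    if (n_tel[a] > 0 && lo_t >= hi_t) {
      stop("infeasible config: adjacent-station travel time leaves no room to plant a teleport ghost inside the solitary delay",
           call. = FALSE)
    }
    lo_s <- 2 * max(2.25 * delay, if (speeds_mh[a] > 0) 1.3 * max_eff / speeds_mh[a] else 0)

    # shuffle the special gap types along the schedule, 4 bouts apart
    specials <- character(0)
    if (n_tel[a] + n_sol[a] > 0) {
      specials <- sample(rep(c("teleport", "solitary"),
                             times = c(n_tel[a], n_sol[a])))
    }
    special_slots <- if (length(specials)) 3 + 4 * (seq_along(specials) - 1) else integer(0)
    placed <- 0L

    st <- sample.int(ns, 1L)
    t_cur <- t0 + runif(1, 0.2, 2) * 3600
    bout_i <- 0L
    repeat {
      # keep every bout wholly inside one deployment window
      if (t_cur > svc0 - 2 * 3600 && t_cur < svc1 + 1) {
        t_cur <- svc1 + runif(1, 0.5, 1.5) * 3600
      }
      if (t_cur > study_end - 2 * 3600) break
      bout_i <- bout_i + 1L
      k <- sample(3:8, 1L)
      times <- t_cur + cumsum(c(0, runif(k - 1, 2, 8) * 60))
      rows[[length(rows) + 1L]] <- data.table(
        animal = animals$animal[a], transmitter = animals$transmitter[a],
        station = stations$station[st], receiver = receivers[st],
        timestamp = times, bin = "genuine")
      bout_end <- max(times)

      # decide the gap to the next bout (and plant a ghost inside it?)
      step <- if (ns == 1L) 0L else if (st == 1L) 1L else if (st == ns) -1L else
        sample(c(-1L, 1L), 1L)
      next_st <- st + step
      want <- if (placed < length(specials) && bout_i >= special_slots[placed + 1L]) {
        specials[placed + 1L]
      } else "regular"

      # a special gap is only usable when the following bout is guaranteed to
      # happen right after it (no service-gap jump, no end-of-study cutoff)
      gap_fits <- function(g) {
        ((bout_end > svc1) ||
           (as.numeric(bout_end - svc0, units = "secs") + (g + 2.5) * 3600 < 0)) &&
          (bout_end + (g + 2.5) * 3600 < study_end)
      }
      gap_h <- NULL
      if (want == "teleport") {
        g <- runif(1, lo_t, hi_t)
        if (gap_fits(g)) {
          ghost_t <- bout_end + runif(1, 1, 3) * 60
          rows[[length(rows) + 1L]] <- data.table(
            animal = animals$animal[a], transmitter = animals$transmitter[a],
            station = stations$station[next_st], receiver = receivers[next_st],
            timestamp = ghost_t, bin = "speed")
          placed <- placed + 1L
          gap_h <- g
        }
      } else if (want == "solitary") {
        g <- runif(1, lo_s, 1.3 * lo_s)
        if (gap_fits(g)) {
          ghost_st <- sample.int(ns, 1L)
          rows[[length(rows) + 1L]] <- data.table(
            animal = animals$animal[a], transmitter = animals$transmitter[a],
            station = stations$station[ghost_st], receiver = receivers[ghost_st],
            timestamp = bout_end + (g / 2) * 3600, bin = "solitary")
          placed <- placed + 1L
          gap_h <- g
        }
      }
      if (is.null(gap_h)) gap_h <- max(gap_floor, runif(1, 0.7, 1.3) * mean_gap_h)
      st <- next_st
      t_cur <- bout_end + gap_h * 3600
    }
    if (placed < length(specials)) {
      stop(sprintf(
        "infeasible config: animal %s's schedule is too short to plant %d ghost(s); increase study_days or detection_rate",
        animals$animal[a], length(specials) - placed), call. = FALSE)
    }
  }
  det <- rbindlist(rows)

  # --- unknown-tag rows: disjoint transmitter namespace, inside windows -----
  if (config$n_unknown_tag > 0) {
    n <- config$n_unknown_tag
    tt <- t0[0L]
    while (length(tt) < n) {
      cand <- t0 + runif(2 * n, 0, config$study_days) * day
      tt <- c(tt, cand[cand < svc0 - 60 | cand > svc1 + 60])
    }
    tt <- tt[seq_len(n)]
    ri <- sample.int(ns, length(tt), replace = TRUE)
    det <- rbind(det, data.table(
      animal = NA_character_,
      transmitter = sprintf("A69-9001-%d", 9000L + seq_along(tt)),
      station = stations$station[ri], receiver = receivers[ri],
      timestamp = tt, bin = "unknown_tag"))
  }

  # --- out-of-window rows: real tags logged during the service gap ----------
  if (config$n_out_of_window > 0) {
    n <- config$n_out_of_window
    span <- as.numeric(svc1 - svc0, units = "secs")
    tt <- svc0 + runif(n, 0.1 * span, 0.9 * span)
    ai <- sample.int(na, n, replace = TRUE)
    ri <- sample.int(ns, n, replace = TRUE)
    det <- rbind(det, data.table(
      animal = animals$animal[ai], transmitter = animals$transmitter[ai],
      station = stations$station[ri], receiver = receivers[ri],
      timestamp = tt, bin = "out_of_window"))
  }

  # receivers log at whole-second resolution
  det[, timestamp := as.POSIXct(floor(as.numeric(timestamp)),
                                origin = "1970-01-01", tz = "UTC")]
  # unique detection keys (collisions are possible only by freak chance)
  setorderv(det, c("timestamp", "transmitter", "receiver"))
  while (anyDuplicated(det, by = c("transmitter", "receiver", "timestamp"))) {
    i <- which(duplicated(det, by = c("transmitter", "receiver", "timestamp")))
    det[i, timestamp := timestamp + 1]
    setorderv(det, c("timestamp", "transmitter", "receiver"))
  }
  det[, uid := sprintf("d%06d", .I)]

  # --- duplicate copies, emitted via a separate "re-download" file ----------
  dup <- det[0L]
  if (config$n_duplicates > 0) {
    pool <- which(det$bin == "genuine")
    dup <- det[sample(pool, min(config$n_duplicates, length(pool)))]
    dup[, bin := "duplicate"]
  }

  # --- write raw detection files -------------------------------------------
  raw_cols <- function(d) {
    out <- if (config$split_datetime) {
      data.table(Date = format(d$timestamp, "%d/%m/%Y", tz = "UTC"),
                 Time = format(d$timestamp, "%H:%M:%S", tz = "UTC"))
    } else {
      data.table(DateTime = format_timestamp(d$timestamp))
    }
    out[, `:=`(Receiver = d$receiver, Transmitter = d$transmitter,
               Sensor = sample.int(100L, nrow(d), replace = TRUE),
               uid = d$uid)]
    out
  }
  write_raw <- function(tab, path) {
    body <- raw_cols(tab)
    con <- file(path, "w")
    on.exit(close(con))
    if (config$preamble_rows > 0) {
      writeLines(rep("# simulated receiver export", config$preamble_rows), con)
    }
    writeLines(paste(names(body), collapse = ","), con)
    if (nrow(body) > 0) {
      writeLines(do.call(paste, c(as.list(body), sep = ",")), con)
    }
    path
  }
  files <- character(0)
  for (i in seq_len(ns)) {
    tab <- det[receiver == receivers[i]]
    if (nrow(tab) == 0L) next
    setorderv(tab, "timestamp")
    f <- file.path(det_dir, sprintf("detections_%s.csv", receivers[i]))
    files <- c(files, write_raw(tab, f))
  }
  if (nrow(dup) > 0L) {
    setorderv(dup, "timestamp")
    files <- c(files, write_raw(dup, file.path(det_dir, "zz_redownload.csv")))
  }

  # --- metadata, distance matrix, truth ------------------------------------
  fwrite(stations, file.path(dir, "spatial.csv"))
  dep_out <- copy(deployments)
  dep_out[, `:=`(start = format_timestamp(start), end = format_timestamp(end))]
  fwrite(dep_out, file.path(dir, "deployments.csv"))
  ani_out <- copy(animals)
  ani_out[, tagged_at := format_timestamp(tagged_at)]
  setcolorder(ani_out, c("transmitter", "animal", "tagged_at"))
  fwrite(ani_out, file.path(dir, "animals.csv"))

  m <- build_distance_matrix(stations)
  mdt <- data.table(station = rownames(m))
  mdt <- cbind(mdt, as.data.table(m))
  fwrite(mdt, file.path(dir, "distance_matrix.csv"))

  truth <- rbind(det, dup)[, .(uid, bin, animal, station,
                               timestamp = format_timestamp(timestamp))]
  fwrite(truth, file.path(dir, "truth.csv"))

  invisible(list(
    dir = dir,
    detections_dir = det_dir,
    files = c(files, file.path(dir, c("spatial.csv", "deployments.csv",
                                      "animals.csv", "distance_matrix.csv",
                                      "truth.csv"))),
    truth = rbind(det, dup)[, .(uid, bin, animal, station, timestamp)],
    config = config
  ))
}
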