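#' Great-circle distance between points (Haversine)
#'
#' Distance in metres on a sphere of radius 6,371,000 m. Adequate for
#' receiver arrays without intervening landmasses; where animals must swim
#' around land, supply an externally computed in-water distance matrix to
#' [filter_by_speed()] instead (see [read_distance_matrix()]).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees; vectorised.
#' @return distances in metres.
#' @export
#' @examples
#' haversine_distance(0, 0, 0, 1)  # one degree of arc on the equator
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  coords <- list(lat1 = lat1, lon1 = lon1, lat2 = lat2, lon2 = lon2)
  for (nm in names(coords)) {
    v <- coords[[nm]]
    lim <- if (grepl("^lat", nm)) 90 else 180
    if (!is.numeric(v) || anyNA(v) || any(abs(v) > lim)) {
      stop(sprintf("`%s` out of range: |latitude| <= 90, |longitude| <= 180", nm),
           call. = FALSE)
    }
  }
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * 6371000 * asin(pmin(1, sqrt(a)))
}

#' Build a station-to-station distance matrix
#'
#' Pairwise Haversine distances between all stations of a validated station
#' table. The result is square, symmetric, zero on the diagonal, with row and
#' column names equal to the station names.
#'
#' @param spatial a station table ([as_station_table()]).
#' @return a numeric matrix of metres with station dimnames.
#' @export
build_distance_matrix <- function(spatial) {
  spa <- as.data.table(spatial)
  check_columns(spa, c("station", "latitude", "longitude"), "build_distance_matrix")
  if (anyDuplicated(spa$station)) stop("station names must be unique", call. = FALSE)
  n <- nrow(spa)
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  d <- haversine_distance(spa$latitude[i], spa$longitude[i],
                          spa$latitude[j], spa$longitude[j])
  m <- matrix(d, nrow = n, ncol = n, byrow = TRUE,
              dimnames = list(spa$station, spa$station))
  diag(m) <- 0
  m
}

#' Validate a (possibly external) distance matrix against the station table
#'
#' External matrices — e.g. in-water least-cost distances computed around
#' landmasses — are accepted if their labels cover all stations, they are
#' symmetric to 1e-6 relative tolerance, non-negative, and zero on the
#' diagonal. Rows/columns are reordered to the station-table order.
#'
#' @param m numeric matrix with station dimnames.
#' @param spatial a station table; `m` must label every one of its stations.
#' @return the validated matrix, reordered to match `spatial$station`.
#' @export
validate_distance_matrix <- function(m, spatial) {
  spa <- as.data.table(spatial)
  stations <- spa$station
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("distance matrix must carry station names as row and column names",
         call. = FALSE)
  }
  missing <- setdiff(stations, intersect(rownames(m), colnames(m)))
  if (length(missing) > 0L) {
    stop(sprintf("distance matrix is missing station(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  m <- m[stations, stations, drop = FALSE]
  storage.mode(m) <- "double"
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) > 1e-6 * scale) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(m < 0) || any(abs(diag(m)) > 1e-6 * scale)) {
    stop("distance matrix must be non-negative with a zero diagonal",
         call. = FALSE)
  }
  diag(m) <- 0
  m
}

#' Read a distance matrix from a delimited file
#'
#' Layout: first row and first column hold the station names; the body is the
#' square table of metres.
#'
#' @param path file to read.
#' @param delimiter field separator (default `","`).
#' @return a numeric matrix with station dimnames.
#' @export
read_distance_matrix <- function(path, delimiter = ",") {
  dt <- fread(path, sep = delimiter, header = TRUE)
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Define a per-animal maximum-speed model
#'
#' Maximum sustainable speed is either a constant for all animals
#' (`base` alone, in m/h by default) or an allometric power law
#' `base * biometric^exponent` scaling with a per-animal biometric such as
#' total body length (in m/s by default, converted to m/h internally — the
#' convention of the critical-swimming-speed literature; e.g. base 0.019,
#' exponent 0.75 on total length in mm gives 8457 m/h for a 616 mm fish).
#'
#' @param base positive base of the speed equation.
#' @param factor_column name of the detection-table column holding the
#'   biometric, or `NULL` for a constant speed.
#' @param exponent exponent applied to the biometric; required iff
#'   `factor_column` is given.
#' @param base_unit `"m/s"` or `"m/h"`; defaults to `"m/s"` with a formula
#'   and `"m/h"` for a constant speed.
#' @return an object of class `speed_model`.
#' @export
speed_model <- function(base, factor_column = NULL, exponent = NULL,
                        base_unit = NULL) {
  check_number(base, "base", function(v) v > 0, "a positive number")
  if (is.null(factor_column) != is.null(exponent)) {
    stop("`exponent` must be supplied iff `factor_column` is supplied",
         call. = FALSE)
  }
  if (!is.null(exponent)) check_number(exponent, "exponent")
  base_unit <- base_unit %||% if (is.null(factor_column)) "m/h" else "m/s"
  if (!base_unit %in% c("m/s", "m/h")) {
    stop('`base_unit` must be "m/s" or "m/h"', call. = FALSE)
  }
  structure(list(base = base, factor_column = factor_column,
                 exponent = exponent, base_unit = base_unit),
            class = "speed_model")
}

#' @export
print.speed_model <- function(x, ...) {
  if (is.null(x$factor_column)) {
    cat(sprintf("<speed_model> constant %g %s (%g m/h)\n", x$base, x$base_unit,
                animal_speed(x)))
  } else {
    cat(sprintf("<speed_model> %g * %s^%g [%s], converted to m/h\n",
                x$base, x$factor_column, x$exponent, x$base_unit))
  }
  invisible(x)
}

#' Compute an animal's maximum speed in metres per hour
#'
#' @param model a [speed_model()].
#' @param biometric_value the animal's biometric (vectorised); required iff
#'   the model has a `factor_column`, forbidden otherwise.
#' @return speed(s) in m/h.
#' @export
#' @examples
#' m <- speed_model(base = 0.019, factor_column = "TL", exponent = 0.75)
#' animal_speed(m, 616)  # ~8457 m/h for a 616 mm fish
animal_speed <- function(model, biometric_value = NULL) {
  stopifnot(inherits(model, "speed_model"))
  if (is.null(model$factor_column)) {
    if (!is.null(biometric_value)) {
      stop("constant-speed model takes no biometric value", call. = FALSE)
    }
    speed <- model$base
  } else {
    if (is.null(biometric_value) || !is.numeric(biometric_value) ||
        anyNA(biometric_value)) {
      stop(sprintf("speed model requires a numeric '%s' value for every animal",
                   model$factor_column), call. = FALSE)
    }
    speed <- model$base * biometric_value^model$exponent
  }
  if (model$base_unit == "m/s") speed <- speed * 3600
  speed
}

#' Minimum in-water distance between two detection footprints
#'
#' Two receivers hear a tag anywhere within their detection ranges, so the
#' least distance an animal must actually cross between consecutive
#' detections is the station distance minus both ranges, floored at zero.
#'
#' @param d station-to-station distance in metres.
#' @param range_a,range_b detection ranges (metres) of the two receivers.
#' @return metres; vectorised.
#' @export
effective_distance <- function(d, range_a, range_b) {
  if (any(d < 0, na.rm = TRUE) || any(range_a < 0) || any(range_b < 0)) {
    stop("distances and ranges must be non-negative", call. = FALSE)
  }
  pmax(0, d - range_a - range_b)
}

#' Specify receiver detection ranges
#'
#' Either one scalar range for every receiver over the whole study, or a
#' table of `(range_category, start, end, range_m)` rows when ranges differ
#' by station category and/or change through time (seasonal noise, biofouling,
#' redeployment at different depths). Per category, the time intervals must
#' not overlap; the range applied to a detection is the one whose closed
#' interval contains the detection timestamp.
#'
#' @param range scalar range in metres (exclusive with `table`).
#' @param table data.frame or path with columns `range_category`, `start`,
#'   `end`, `range_m` (exclusive with `range`).
#' @param datetime_formats,tz,delimiter parsing options when `table` is used.
#' @return an object of class `range_spec`.
#' @export
range_spec <- function(range = NULL, table = NULL, datetime_formats = "ymd HMS",
                       tz = "UTC", delimiter = ",") {
  if (is.null(range) == is.null(table)) {
    stop("supply exactly one of `range` (scalar) or `table`", call. = FALSE)
  }
  if (!is.null(range)) {
    check_number(range, "range", function(v) v >= 0, "a non-negative number of metres")
    return(structure(list(kind = "scalar", range = range), class = "range_spec"))
  }
  tab <- read_meta(table, delimiter)
  check_columns(tab, c("range_category", "start", "end", "range_m"), "range table")
  tab <- tab[, .(range_category = as.character(range_category),
                 start = parse_timestamps(start, datetime_formats, tz, "range start"),
                 end = parse_timestamps(end, datetime_formats, tz, "range end"),
                 range_m = as.numeric(range_m))]
  if (any(tab$range_m < 0) || anyNA(tab$range_m)) {
    stop("ranges must be non-negative metres", call. = FALSE)
  }
  if (any(tab$start >= tab$end)) {
    stop("range intervals must have start < end", call. = FALSE)
  }
  ov <- copy(tab)
  setorderv(ov, c("range_category", "start"))
  bad <- ov[, .(overlap = any(shift(end)[-1] >= start[-1])), by = range_category][
    overlap == TRUE, range_category]
  if (length(bad) > 0L) {
    stop(sprintf("overlapping range intervals for category(ies): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  structure(list(kind = "table", table = tab), class = "range_spec")
}

# Range in metres applying to each (category, timestamp) pair; errors when a
# detection falls outside every interval of its category.
lookup_range <- function(spec, category, timestamp) {
  stopifnot(inherits(spec, "range_spec"))
  if (spec$kind == "scalar") return(rep(spec$range, length(timestamp)))
  probe <- data.table(range_category = as.character(category),
                      timestamp = timestamp, .row__ = seq_along(timestamp))
  hit <- spec$table[probe,
                    on = .(range_category, start <= timestamp, end >= timestamp),
                    .(.row__ = i..row__, range_m = x.range_m)]
  out <- hit$range_m[order(hit$.row__)]
  miss <- which(is.na(out))
  if (length(miss) > 0L) {
    stop(sprintf(
      "no detection range defined for category '%s' at %s (and %d more?)",
      category[miss[1L]], format_timestamp(timestamp[miss[1L]]),
      length(miss) - 1L), call. = FALSE)
  }
  out
}

#' Remove detections implying impossible movement speeds
#'
#' Per animal, detections are ordered by time (ties broken by receiver, then
#' station, name). For each consecutive pair of currently retained detections,
#' the required speed is the effective distance between their stations (see
#' [effective_distance()]) divided by the elapsed time; a zero time gap over a
#' positive effective distance requires infinite speed. The *later* member of
#' a violating pair is flagged — the earlier one was already vetted against
#' its own predecessor. Each iteration computes all flags against the
#' currently retained rows, removes every flagged row at once, and repeats
#' until an iteration flags nothing; removal changes adjacency, which is why
#' the process must reiterate. On return, no consecutive retained pair
#' violates the speed rule or, if set, the `max_distance` rule.
#'
#' @param detections attributed detection table with `animal`, `station`,
#'   `timestamp` columns (plus the model's `factor_column` and, for a range
#'   table, `range_category`).
#' @param dist_matrix station distance matrix covering every station present.
#' @param model a [speed_model()].
#' @param ranges a [range_spec()].
#' @param max_distance optional metres; consecutive detections further apart
#'   than this (raw station distance) are infeasible regardless of speed.
#' @param range_ends subtract the detection ranges at `"both"` endpoints of a
#'   movement (default, the conservative bound) or only at the `"arrival"`
#'   receiver.
#' @return `list(kept = , removed = , iterations = )`; rows keep their input
#'   order, the parts partition the input, and `iterations >= 1` counts sweeps
#'   including the final one that finds nothing.
#' @export
filter_by_speed <- function(detections, dist_matrix, model, ranges,
                            max_distance = NULL,
                            range_ends = c("both", "arrival")) {
  range_ends <- match.arg(range_ends)
  stopifnot(inherits(model, "speed_model"), inherits(ranges, "range_spec"))
  det <- as.data.table(detections)
  check_columns(det, c("animal", "station", "timestamp"), "filter_by_speed")
  if (!is.null(max_distance)) {
    check_number(max_distance, "max_distance", function(v) v > 0,
                 "a positive number of metres")
  }

  missing_st <- setdiff(unique(det$station), rownames(dist_matrix))
  if (length(missing_st) > 0L) {
    stop(sprintf("station(s) absent from the distance matrix: %s",
                 paste(missing_st, collapse = ", ")), call. = FALSE)
  }

  det <- copy(det)
  det[, .row__ := .I]
  if (nrow(det) == 0L) {
    det[, .row__ := NULL]
    return(list(kept = det[], removed = det[0L], iterations = 1L))
  }

  # per-row maximum speed (constant per animal)
  if (is.null(model$factor_column)) {
    det[, .speed__ := animal_speed(model)]
  } else {
    check_columns(det, model$factor_column, "filter_by_speed")
    val <- as.numeric(det[[model$factor_column]])
    bad <- det$animal[is.na(val)]
    if (length(bad) > 0L) {
      stop(sprintf("missing '%s' biometric for animal(s): %s",
                   model$factor_column,
                   paste(unique(bad), collapse = ", ")), call. = FALSE)
    }
    det[, .speed__ := animal_speed(model, val)]
  }

  # per-row detection range at the detection's own time
  if (ranges$kind == "table") check_columns(det, "range_category", "filter_by_speed")
  cat_col <- if (ranges$kind == "table") det$range_category else rep("", nrow(det))
  det[, .range__ := lookup_range(ranges, cat_col, timestamp)]

  tie_col <- intersect(c("receiver", "station"), names(det))[1L]
  ord <- copy(det)
  setorderv(ord, c("animal", "timestamp", tie_col))
  ord[, .t__ := as.numeric(timestamp)]

  retained <- rep(TRUE, nrow(ord))
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    sub <- ord[retained]
    if (nrow(sub) == 0L) break
    sub[, `:=`(p_station = shift(station), p_t = shift(.t__),
               p_range = shift(.range__)), by = animal]
    first <- is.na(sub$p_station)
    d <- rep(0, nrow(sub))
    d[!first] <- dist_matrix[cbind(sub$p_station[!first], sub$station[!first])]
    eff <- if (range_ends == "both") {
      effective_distance(d, ifelse(first, 0, sub$p_range), sub$.range__)
    } else {
      effective_distance(d, 0, sub$.range__)
    }
    dt_h <- (sub$.t__ - sub$p_t) / 3600
    required <- eff / dt_h          # 0/0 handled below; x/0 = Inf as intended
    required[eff == 0] <- 0
    viol <- !first & (required > sub$.speed__)
    if (!is.null(max_distance)) viol <- viol | (!first & d > max_distance)
    if (!any(viol)) break
    retained[which(retained)[viol]] <- FALSE
  }

  flagged_rows <- ord$.row__[!retained]
  det[, .removed__ := .row__ %in% flagged_rows]
  kept <- det[.removed__ == FALSE]
  removed <- det[.removed__ == TRUE]
  aux <- c(".row__", ".speed__", ".range__", ".removed__")
  kept[, (aux) := NULL]
  removed[, (aux) := NULL]
  list(kept = kept[], removed = removed[], iterations = iterations)
}
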