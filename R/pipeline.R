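#' Run the full detection-cleaning pipeline
#'
#' Convenience wrapper chaining the five stages: compile raw files, attribute
#' stations via deployment windows, attribute animals via tagging history,
#' remove solitary detections, remove speed-infeasible detections. Every
#' stage partitions its input exhaustively; the returned report accounts for
#' every compiled row.
#'
#' @param detections_folder folder of raw detection files.
#' @param mapping a [column_mapping()] for the raw files.
#' @param deployments,spatial,animals validated metadata tables (see
#'   [as_deployment_table()], [as_station_table()], [as_animal_table()]).
#' @param delay solitary-rule delay in hours.
#' @param model a [speed_model()].
#' @param ranges a [range_spec()].
#' @param per_receiver solitary grouping per receiver (default) or array-wide.
#' @param dist_matrix optional externally supplied station distance matrix;
#'   by default the Haversine matrix is built from `spatial`.
#' @param max_distance optional hard cap (metres) on consecutive movements.
#' @param discard_first hours to discard after each tagging event.
#' @param extension,batch_size,dedupe passed to [compile_detections()].
#' @param out_dir optional directory; when given, the kept table, every
#'   discard bin and the JSON partition report are written there as CSV/JSON.
#' @return a list with `kept`, `bins` (named list of discard tables:
#'   `duplicates`, `out_of_deployment`, `unknown_tag`, `solitary`, `speed`),
#'   `speed_iterations` and `report` (a [partition_report()]).
#' @export
run_pipeline <- function(detections_folder, mapping, deployments, spatial,
                         animals, delay, model, ranges, per_receiver = TRUE,
                         dist_matrix = NULL, max_distance = NULL,
                         discard_first = 0, extension = ".csv",
                         batch_size = NULL, dedupe = TRUE, out_dir = NULL) {
  comp <- compile_detections(detections_folder, mapping, extension = extension,
                             batch_size = batch_size, dedupe = dedupe)
  rep_ <- partition_report()
  rep_ <- report_stage(rep_, "compile", comp$report[["input"]],
                       comp$report[["kept"]],
                       duplicates = comp$report[["duplicates"]])

  st <- attribute_stations(comp$detections, deployments, spatial)
  rep_ <- report_stage(rep_, "stations", nrow(comp$detections),
                       nrow(st$attributed),
                       out_of_deployment = nrow(st$out_of_deployment))

  an <- attribute_animals(st$attributed, animals, discard_first = discard_first)
  rep_ <- report_stage(rep_, "animals", nrow(st$attributed),
                       nrow(an$attributed), unknown_tag = nrow(an$unknown))

  so <- find_solitary(an$attributed, delay = delay, per_receiver = per_receiver)
  rep_ <- report_stage(rep_, "solitary", nrow(an$attributed), nrow(so$kept),
                       solitary = nrow(so$solitary))

  if (is.null(dist_matrix)) {
    dist_matrix <- build_distance_matrix(spatial)
  } else {
    dist_matrix <- validate_distance_matrix(dist_matrix, spatial)
  }
  sp <- filter_by_speed(so$kept, dist_matrix, model, ranges,
                        max_distance = max_distance)
  rep_ <- report_stage(rep_, "speed", nrow(so$kept), nrow(sp$kept),
                       speed = nrow(sp$removed))

  out <- list(
    kept = sp$kept,
    bins = list(duplicates = comp$duplicates,
                out_of_deployment = st$out_of_deployment,
                unknown_tag = an$unknown,
                solitary = so$solitary,
                speed = sp$removed),
    speed_iterations = sp$iterations,
    report = rep_
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_detections_csv <- function(dt, name) {
      d <- copy(as.data.table(dt))
      if ("timestamp" %in% names(d)) d[, timestamp := format_timestamp(timestamp)]
      fwrite(d, file.path(out_dir, name))
    }
    write_detections_csv(out$kept, "detections_kept.csv")
    for (nm in names(out$bins)) {
      write_detections_csv(out$bins[[nm]], sprintf("removed_%s.csv", nm))
    }
    write_partition_report(rep_, file.path(out_dir, "report.json"))
  }
  out
}
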