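# Exhaustive accounting of where every input row ended up. Each pipeline
# stage appends one entry; input = kept + sum(discard bins) is enforced at
# append time, so a stage that loses or double-counts rows fails immediately.

#' Create an empty partition report
#'
#' @return an object of class `partition_report` (a list of stage entries).
#' @export
partition_report <- function() {
  structure(list(stages = list()), class = "partition_report")
}

#' Record one pipeline stage in a partition report
#'
#' @param report a [partition_report()].
#' @param stage stage name (e.g. `"compile"`, `"solitary"`).
#' @param input number of rows entering the stage.
#' @param kept number of rows kept.
#' @param ... named discard-bin counts (e.g. `duplicates = 5`).
#' @return the updated report.
#' @export
report_stage <- function(report, stage, input, kept, ...) {
  stopifnot(inherits(report, "partition_report"))
  bins <- c(...)
  if (input != kept + sum(bins)) {
    stop(sprintf(
      "stage '%s' does not partition its input: input %d != kept %d + discarded %d",
      stage, input, kept, sum(bins)), call. = FALSE)
  }
  entry <- list(stage = stage, input = input, kept = kept,
                bins = as.list(bins),
                recorded_at = format_timestamp(Sys.time()))
  report$stages[[stage]] <- entry
  report
}

#' Write a partition report as JSON
#'
#' @param report a [partition_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition_report <- function(report, path) {
  stopifnot(inherits(report, "partition_report"))
  jsonlite::write_json(report$stages, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.partition_report <- function(x, ...) {
  cat("<partition_report>\n")
  for (s in x$stages) {
    bins <- if (length(s$bins)) {
      paste(sprintf("%s %d", names(s$bins), unlist(s$bins)), collapse = ", ")
    } else "none"
    cat(sprintf("  %-12s in %7d  kept %7d  removed: %s\n",
                s$stage, s$input, s$kept, bins))
  }
  invisible(x)
}
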