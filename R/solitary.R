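#' Partition solitary detections
#'
#' When an animal is within range of a receiver it usually stays long enough
#' to log several detections, so a detection with no same-animal neighbour
#' close in time is likely spurious (a code collision or noise). A detection
#' is *solitary* when the gap to the previous detection in its group is at
#' least `delay` hours AND the gap to the next is at least `delay` hours; a
#' missing neighbour counts as an infinite gap, and detections sharing a
#' timestamp have gap zero and rescue each other. The grouping is always per
#' animal; with `per_receiver = TRUE` (the stricter, per-receiver rule) the
#' receiver is part of the group too, so a neighbour only rescues a detection
#' logged on the same receiver.
#'
#' Flags are computed once on the full input and all flagged rows are removed
#' in a single pass. Because a rescuing neighbour lies strictly within `delay`
#' and therefore can never itself be solitary, the filter is idempotent:
#' re-running it on its own kept output flags nothing.
#'
#' @param detections attributed detection table with `animal`, `timestamp`
#'   and, when `per_receiver = TRUE`, `receiver` columns.
#' @param delay window half-width in hours (> 0). A gap of exactly `delay`
#'   does not rescue: ties at the boundary are solitary.
#' @param per_receiver group per `(animal, receiver)` (default `TRUE`) or per
#'   animal across the whole array (`FALSE`). Array-wide grouping can only add
#'   neighbours, so it never flags more rows than the per-receiver rule.
#' @return `list(kept = , solitary = )`, both in input row order;
#'   `nrow(kept) + nrow(solitary) == nrow(detections)`.
#' @export
#' @examples
#' det <- data.frame(
#'   animal = "F1", receiver = "R1",
#'   timestamp = as.POSIXct("2021-06-01", tz = "UTC") + c(0, 600, 7200)
#' )
#' find_solitary(det, delay = 1)$solitary  # only the detection 2 h out
find_solitary <- function(detections, delay, per_receiver = TRUE) {
  check_number(delay, "delay", function(v) v > 0, "a positive number of hours")
  det <- as.data.table(detections)
  group_cols <- if (isTRUE(per_receiver)) c("animal", "receiver") else "animal"
  check_columns(det, c(group_cols, "timestamp"), "find_solitary")

  det <- copy(det)
  det[, .row__ := .I]
  ord <- copy(det)
  setorderv(ord, c(group_cols, "timestamp"))
  delay_s <- delay * 3600
  ord[, .solo__ := {
    tt <- as.numeric(timestamp)
    gap_prev <- c(Inf, diff(tt))
    gap_next <- c(diff(tt), Inf)
    gap_prev >= delay_s & gap_next >= delay_s
  }, by = group_cols]

  det[ord, on = ".row__", .solo__ := i..solo__]
  kept <- det[.solo__ == FALSE]
  solitary <- det[.solo__ == TRUE]
  kept[, c(".row__", ".solo__") := NULL]
  solitary[, c(".row__", ".solo__") := NULL]
  list(kept = kept[], solitary = solitary[])
}
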