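#' Receiver-compartment sampling schedule
#'
#' Records when samples are drawn from the receiver compartment, how much
#' volume is removed each time, and how much blank medium is added back.
#' The standard bidirectional design samples half the receiver volume at
#' 0.5, 1 and 1.2 h with full medium replacement, plus a terminal sample at
#' 2 h with no replacement.
#'
#' @param time sampling times in hours since dosing, strictly increasing.
#' @param removed_volume volume drawn at each time, in mL (recycled).
#' @param replaced_volume blank medium added back after each draw, in mL
#'   (recycled; defaults to `removed_volume` except 0 at the final, terminal
#'   sample).
#' @return An object of class `"sampling_schedule"` (a data frame with
#'   columns `time`, `removed_volume`, `replaced_volume`).
#' @seealso [default_schedule()], [validate_schedule()]
#' @export
sampling_schedule <- function(time, removed_volume, replaced_volume = NULL) {
  stopifnot(is.numeric(time), length(time) >= 1L, is.numeric(removed_volume))
  removed_volume <- rep_len(removed_volume, length(time))
  if (is.null(replaced_volume)) {
    replaced_volume <- removed_volume
    replaced_volume[length(time)] <- 0  # terminal sample: nothing added back
  } else {
    replaced_volume <- rep_len(replaced_volume, length(time))
  }
  sched <- data.frame(time = time, removed_volume = removed_volume,
                      replaced_volume = replaced_volume)
  class(sched) <- c("sampling_schedule", "data.frame")
  sched
}

#' Default half-volume sampling schedule
#'
#' Half the receiver volume at 0.5, 1 and 1.2 h with replacement, terminal
#' half-volume sample at 2 h without replacement.
#'
#' @param geometry a [transwell_geometry()].
#' @param receiver_side which compartment is the receiver.
#' @param times sampling times in hours.
#' @return A validated `"sampling_schedule"`.
#' @export
default_schedule <- function(geometry = transwell_geometry(),
                             receiver_side = c("basolateral", "apical"),
                             times = c(0.5, 1, 1.2, 2)) {
  receiver_side <- match.arg(receiver_side)
  v <- if (receiver_side == "basolateral") geometry$basolateral_volume else
    geometry$apical_volume
  validate_schedule(sampling_schedule(times, v / 2), geometry, receiver_side)
}

#' Validate a sampling schedule against an insert geometry
#'
#' Checks that sampling times are strictly increasing, that no draw exceeds
#' the receiver volume, and records the terminal sample. Validation is
#' idempotent: validating an already-validated schedule for the same geometry
#' and side returns it unchanged.
#'
#' @param schedule a [sampling_schedule()].
#' @param geometry a [transwell_geometry()].
#' @param receiver_side which compartment is the receiver
#'   (`"basolateral"` for apical-to-basolateral transport, `"apical"` for the
#'   reverse).
#' @return The schedule with validation metadata attached.
#' @export
validate_schedule <- function(schedule, geometry = transwell_geometry(),
                              receiver_side = c("basolateral", "apical")) {
  receiver_side <- match.arg(receiver_side)
  stopifnot(inherits(schedule, "sampling_schedule"),
            inherits(geometry, "transwell_geometry"))
  v <- if (receiver_side == "basolateral") geometry$basolateral_volume else
    geometry$apical_volume
  if (isTRUE(attr(schedule, "validated")) &&
      identical(attr(schedule, "receiver_side"), receiver_side) &&
      identical(attr(schedule, "receiver_volume"), v))
    return(schedule)
  t <- schedule$time
  if (any(diff(t) <= 0)) stop("schedule error: sampling times must be strictly increasing")
  if (any(t <= 0)) stop("schedule error: sampling times must be positive")
  if (any(schedule$removed_volume <= 0))
    stop("schedule error: removed_volume must be positive")
  if (any(schedule$removed_volume > v + 1e-12))
    stop(sprintf("schedule error: removal of %g mL exceeds receiver volume %g mL",
                 max(schedule$removed_volume), v))
  if (any(schedule$replaced_volume < 0))
    stop("schedule error: replaced_volume must be >= 0")
  attr(schedule, "validated") <- TRUE
  attr(schedule, "receiver_side") <- receiver_side
  attr(schedule, "receiver_volume") <- v
  attr(schedule, "terminal_time") <- t[length(t)]
  schedule
}
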