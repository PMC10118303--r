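#' Define a home-cage session schedule
#'
#' A schedule fixes the phase structure of a discrimination/reversal session:
#' an acquisition phase in which the left hole is rewarded, followed by a
#' reversal phase in which the right hole is rewarded, overlaid with a
#' light:dark cycle. Phase and cycle windows are half-open on whole hours:
#' hour `h` covers `[h, h + 1)` and an event exactly on a boundary belongs to
#' the later interval.
#'
#' @param session_hours total session duration in hours (default 90).
#' @param acquisition_hours end of the acquisition phase; acquisition spans
#'   `[0, acquisition_hours)` hours with the left hole correct, reversal spans
#'   `[acquisition_hours, session_hours)` with the right hole correct
#'   (default 49).
#' @param dark_onset session hour at which the first dark phase starts
#'   (default 3, so dark phases fall on hours 3-15, 27-39, 51-63, 75-87).
#' @param dark_hours,light_hours duration of the dark and light halves of the
#'   cycle in hours (defaults 12 and 12).
#'
#' @return An object of class `session_schedule`.
#' @examples
#' sched <- session_schedule()
#' correct_hole(sched, c(10, 60))   # "left" "right"
#' is_dark_hour(sched, 0:5)
#' @export
session_schedule <- function(session_hours = 90, acquisition_hours = 49,
                             dark_onset = 3, dark_hours = 12,
                             light_hours = 12) {
  stopifnot(
    is.numeric(session_hours), length(session_hours) == 1L, session_hours > 0,
    is.numeric(acquisition_hours), length(acquisition_hours) == 1L,
    acquisition_hours > 0, acquisition_hours < session_hours,
    is.numeric(dark_onset), dark_onset >= 0,
    dark_hours > 0, light_hours > 0
  )
  structure(
    list(
      session_hours = session_hours,
      acquisition_hours = acquisition_hours,
      dark_onset = dark_onset,
      dark_hours = dark_hours,
      light_hours = light_hours
    ),
    class = "session_schedule"
  )
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf(
    "session schedule: %g h total; acquisition [0,%g) h (correct=left); reversal [%g,%g) h (correct=right)\n",
    x$session_hours, x$acquisition_hours, x$acquisition_hours, x$session_hours
  ))
  cat(sprintf(
    "light:dark cycle: first dark onset at hour %g, %g h dark / %g h light\n",
    x$dark_onset, x$dark_hours, x$light_hours
  ))
  invisible(x)
}

#' Task phase containing a session time
#'
#' @param schedule a [session_schedule()].
#' @param t_hours numeric vector of session times in hours.
#' @return Character vector, `"acquisition"` or `"reversal"`.
#' @export
phase_of <- function(schedule, t_hours) {
  stopifnot(inherits(schedule, "session_schedule"))
  ifelse(t_hours < schedule$acquisition_hours, "acquisition", "reversal")
}

#' Correct hole at a session time
#'
#' The left hole is correct throughout acquisition and the right hole
#' throughout reversal.
#'
#' @inheritParams phase_of
#' @return Character vector, `"left"` or `"right"`.
#' @export
correct_hole <- function(schedule, t_hours) {
  ifelse(phase_of(schedule, t_hours) == "acquisition", "left", "right")
}

#' Is a session hour inside a dark phase?
#'
#' @param schedule a [session_schedule()].
#' @param hour numeric vector of session hours (may be fractional).
#' @return Logical vector.
#' @export
is_dark_hour <- function(schedule, hour) {
  stopifnot(inherits(schedule, "session_schedule"))
  cycle <- schedule$dark_hours + schedule$light_hours
  ((hour - schedule$dark_onset) %% cycle) < schedule$dark_hours
}

#' End hour of a criterion scope
#'
#' @param schedule a [session_schedule()].
#' @param scope `"acquisition"` or `"reversal"`.
#' @return Scope end in session hours.
#' @keywords internal
scope_end_hour <- function(schedule, scope) {
  if (scope == "acquisition") schedule$acquisition_hours else schedule$session_hours
}
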