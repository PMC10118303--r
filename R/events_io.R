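#' Event-log format
#'
#' Entry events are stored as a plain data frame with columns `animal_id`
#' (character), `t_seconds` (numeric seconds since session start) and `hole`
#' (one of `"left"`, `"middle"`, `"right"`). On disk the log is a UTF-8 CSV
#' with exactly that header. All readers/writers keep events sorted by
#' `(animal_id, t_seconds)`.
#'
#' @name event_log
NULL

HOLE_LEVELS <- c("left", "middle", "right")
EVENT_LOG_HEADER <- c("animal_id", "t_seconds", "hole")

#' Read an entry-event log
#'
#' @param path path to a CSV file with header `animal_id,t_seconds,hole`.
#' @return Data frame of events sorted by animal and time.
#'
#' Malformed rows are hard errors: an unknown hole label or a non-numeric /
#' negative timestamp is reported with its line number (header = line 1);
#' non-monotonic timestamps within an animal are reported naming the animal.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path)
  ev <- utils::read.csv(path, colClasses = c("character", "numeric", "character"),
                        strip.white = TRUE)
  if (!identical(names(ev), EVENT_LOG_HEADER)) {
    stop("event log header must be '", paste(EVENT_LOG_HEADER, collapse = ","),
         "', got '", paste(names(ev), collapse = ","), "'")
  }
  bad_hole <- which(!ev$hole %in% HOLE_LEVELS)
  if (length(bad_hole)) {
    stop("unknown hole label(s) at line(s) ",
         paste(bad_hole + 1L, collapse = ", "), ": ",
         paste(unique(ev$hole[bad_hole]), collapse = ", "))
  }
  bad_t <- which(is.na(ev$t_seconds) | ev$t_seconds < 0)
  if (length(bad_t)) {
    stop("missing or negative t_seconds at line(s) ",
         paste(bad_t + 1L, collapse = ", "))
  }
  # timestamps must be strictly increasing per animal in file order
  for (id in unique(ev$animal_id)) {
    ts <- ev$t_seconds[ev$animal_id == id]
    if (any(diff(ts) <= 0)) {
      stop("non-monotonic timestamps for animal '", id, "'")
    }
  }
  ev[order(ev$animal_id, ev$t_seconds), , drop = FALSE]
}

#' Write an entry-event log
#'
#' Rows are sorted by `(animal_id, t_seconds)` before writing so that output
#' is deterministic; writing the same events twice yields byte-identical
#' files. An empty event set produces a header-only file.
#'
#' @param events event data frame (see [event_log]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  stopifnot(all(EVENT_LOG_HEADER %in% names(events)))
  ev <- events[order(events$animal_id, events$t_seconds),
               EVENT_LOG_HEADER, drop = FALSE]
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an event log against a schedule
#'
#' A reporting operation: it never throws on content problems, it lists them.
#' An empty report means the event-log invariants hold (all times inside the
#' session, no duplicated timestamps within an animal, known hole labels).
#'
#' @param events event data frame.
#' @param schedule a [session_schedule()].
#' @return Data frame with columns `animal_id`, `t_seconds`, `issue`;
#'   zero rows when the log is valid.
#' @export
validate_event_log <- function(events, schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  issues <- list()
  add <- function(id, t, what) {
    data.frame(animal_id = id, t_seconds = t, issue = what,
               stringsAsFactors = FALSE)
  }
  end_s <- schedule$session_hours * 3600
  out <- events$t_seconds < 0 | events$t_seconds > end_s
  if (any(out)) {
    issues <- c(issues, list(add(events$animal_id[out], events$t_seconds[out],
                                 "time out of session range")))
  }
  bad_hole <- !events$hole %in% HOLE_LEVELS
  if (any(bad_hole)) {
    issues <- c(issues, list(add(events$animal_id[bad_hole],
                                 events$t_seconds[bad_hole],
                                 "unknown hole label")))
  }
  key <- paste(events$animal_id, events$t_seconds)
  dup <- duplicated(key)
  if (any(dup)) {
    issues <- c(issues, list(add(events$animal_id[dup], events$t_seconds[dup],
                                 "duplicated timestamp within animal")))
  }
  if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(animal_id = character(), t_seconds = numeric(),
               issue = character(), stringsAsFactors = FALSE)
  }
}

#' Bin entry events into hourly counts
#'
#' Produces one row per animal and session hour with hole counts,
#' correct/incorrect counts (correctness judged from the phase containing each
#' event time), the phase label and the light/dark flag. Hour `h` covers
#' `[h, h + 1)`; hours with no entries carry zero counts. Binning conserves
#' the total event count and is idempotent: correctness depends only on
#' `(t, schedule)`.
#'
#' @param events validated event data frame.
#' @param schedule a [session_schedule()].
#' @return Data frame of class `hourly_bins` with columns `animal_id`, `hour`,
#'   `n_left`, `n_middle`, `n_right`, `n_correct`, `n_incorrect`, `n_total`,
#'   `phase`, `dark`. The schedule is attached as attribute `"schedule"`.
#' @export
bin_events_hourly <- function(events, schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  H <- as.integer(schedule$session_hours)
  a <- factor(events$animal_id)
  t_h <- events$t_seconds / 3600
  hr <- factor(pmin(floor(t_h), H - 1L), levels = 0:(H - 1L))
  hole <- factor(events$hole, levels = HOLE_LEVELS)
  corr <- factor(events$hole == correct_hole(schedule, t_h),
                 levels = c(FALSE, TRUE))
  tab <- table(a, hr, hole)
  ctab <- table(a, hr, corr)
  # as.vector flattens animal-fastest, matching expand.grid order
  bins <- expand.grid(animal_id = levels(a), hour = 0:(H - 1L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bins$n_left <- as.vector(tab[, , "left"])
  bins$n_middle <- as.vector(tab[, , "middle"])
  bins$n_right <- as.vector(tab[, , "right"])
  bins$n_correct <- as.vector(ctab[, , "TRUE"])
  bins$n_incorrect <- as.vector(ctab[, , "FALSE"])
  bins$n_total <- bins$n_left + bins$n_middle + bins$n_right
  bins$phase <- phase_of(schedule, bins$hour)
  bins$dark <- is_dark_hour(schedule, bins$hour)
  bins <- bins[order(bins$animal_id, bins$hour), , drop = FALSE]
  rownames(bins) <- NULL
  attr(bins, "schedule") <- schedule
  class(bins) <- c("hourly_bins", "data.frame")
  bins
}
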