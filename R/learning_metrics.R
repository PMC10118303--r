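#' Learning index from correct/incorrect counts
#'
#' The learning index is (correct - incorrect) / total entries. It is bounded
#' in \[-1, 1\] and undefined (`NA`) when there are no entries: a zero index
#' asserts chance-level performance, which absent data cannot support.
#'
#' @param n_correct,n_incorrect non-negative counts.
#' @return Numeric vector of indices, `NA` where the total count is zero.
#' @export
learning_index <- function(n_correct, n_incorrect) {
  total <- n_correct + n_incorrect
  ifelse(total > 0, (n_correct - n_incorrect) / total, NA_real_)
}

#' Cumulative learning index through a session hour
#'
#' Aggregates counts over the hours of the phase containing `through_hour`,
#' from phase start up to and including hour `floor(through_hour)`, and
#' returns the learning index of the pooled counts per animal.
#'
#' @param bins an `hourly_bins` data frame from [bin_events_hourly()].
#' @param through_hour session hour (inclusive of that hour's bin).
#' @return Data frame with columns `animal_id`, `index`,
#'   `n_correct`, `n_incorrect`.
#' @export
cumulative_learning_index <- function(bins, through_hour) {
  stopifnot(inherits(bins, "hourly_bins"),
            through_hour >= 0, through_hour < max(bins$hour) + 1)
  h <- floor(through_hour)
  ph <- bins$phase[match(h, bins$hour)]
  sel <- bins$phase == ph & bins$hour <= h
  cc <- tapply(bins$n_correct[sel], bins$animal_id[sel], sum)
  ci <- tapply(bins$n_incorrect[sel], bins$animal_id[sel], sum)
  data.frame(animal_id = names(cc),
             index = as.numeric(learning_index(cc, ci)),
             n_correct = as.numeric(cc), n_incorrect = as.numeric(ci),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hourly (independent) and cumulative learning-index series
#'
#' The independent index is computed per hour from that hour's counts; the
#' cumulative index restarts at each phase boundary and pools counts from
#' phase start. Hours with zero entries have an `NA` independent index; the
#' cumulative index is `NA` until the first entry of the phase.
#'
#' @param bins an `hourly_bins` data frame.
#' @return Data frame: `animal_id`, `hour`, `phase`, `dark`, `n_correct`,
#'   `n_incorrect`, `n_total`, `index_hourly`, `index_cumulative`.
#' @export
hourly_learning_index <- function(bins) {
  stopifnot(inherits(bins, "hourly_bins"))
  b <- bins[order(bins$animal_id, bins$hour), , drop = FALSE]
  key <- interaction(b$animal_id, b$phase, drop = TRUE)
  cum_c <- stats::ave(b$n_correct, key, FUN = cumsum)
  cum_i <- stats::ave(b$n_incorrect, key, FUN = cumsum)
  data.frame(
    animal_id = b$animal_id, hour = b$hour, phase = b$phase, dark = b$dark,
    n_correct = b$n_correct, n_incorrect = b$n_incorrect, n_total = b$n_total,
    index_hourly = learning_index(b$n_correct, b$n_incorrect),
    index_cumulative = learning_index(cum_c, cum_i),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Learning index over an hour window
#'
#' Pools entries over whole hours in the half-open window
#' `[hour_window[1], hour_window[2])` and returns the learning index per
#' animal. The window must lie within a single phase; windows spanning the
#' acquisition/reversal boundary are rejected.
#'
#' @param bins an `hourly_bins` data frame.
#' @param hour_window numeric length-2, `[start, end)` in session hours.
#' @return Data frame with columns `animal_id`, `index`, `n_entries`.
#' @export
windowed_learning_index <- function(bins, hour_window) {
  stopifnot(inherits(bins, "hourly_bins"), length(hour_window) == 2L,
            hour_window[1] < hour_window[2])
  sel <- bins$hour >= hour_window[1] & bins$hour < hour_window[2]
  if (!any(sel)) stop("hour window contains no session hours")
  phases <- unique(bins$phase[sel])
  if (length(phases) > 1L) {
    stop("hour window [", hour_window[1], ",", hour_window[2],
         ") spans a phase boundary")
  }
  cc <- tapply(bins$n_correct[sel], bins$animal_id[sel], sum)
  ci <- tapply(bins$n_incorrect[sel], bins$animal_id[sel], sum)
  data.frame(animal_id = names(cc),
             index = as.numeric(learning_index(cc, ci)),
             n_entries = as.numeric(cc + ci),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Initial learning rate (first acquisition dark phase)
#'
#' Windowed learning index over the first dark phase of acquisition,
#' by default session hours \[3, 13) — ten hourly bins.
#'
#' @param bins an `hourly_bins` data frame.
#' @param hour_window window in session hours (default `c(3, 13)`).
#' @return As [windowed_learning_index()].
#' @export
initial_learning_rate <- function(bins, hour_window = c(3, 13)) {
  windowed_learning_index(bins, hour_window)
}

#' Cognitive flexibility (first reversal dark phase)
#'
#' Windowed learning index over the first dark phase of reversal, by default
#' session hours \[51, 61) — ten hourly bins. It captures both extinction of
#' the previously rewarded response and relearning of the new contingency:
#' perseverating animals score low because previously correct (left) and
#' middle entries count as errors after the reversal.
#'
#' @param bins an `hourly_bins` data frame.
#' @param hour_window window in session hours (default `c(51, 61)`).
#' @return As [windowed_learning_index()].
#' @export
cognitive_flexibility <- function(bins, hour_window = c(51, 61)) {
  windowed_learning_index(bins, hour_window)
}

#' Extinction curves over the first reversal dark phase
#'
#' Per animal and hour in the window, the percentage of entries to the
#' previously rewarded left hole, to the middle hole, and total errors
#' (left + middle) among that hour's entries. Percentages are on the 0-100
#' scale, `%errors = %left + %middle`, and `%right = 100 - %errors`. Hours
#' with no entries are `NA`.
#'
#' @param bins an `hourly_bins` data frame.
#' @param hour_window window in session hours, within reversal
#'   (default `c(51, 61)`).
#' @return Data frame: `animal_id`, `hour`, `n_total`, `pct_left`,
#'   `pct_middle`, `pct_errors`.
#' @export
extinction_curves <- function(bins, hour_window = c(51, 61)) {
  stopifnot(inherits(bins, "hourly_bins"), length(hour_window) == 2L)
  sel <- bins$hour >= hour_window[1] & bins$hour < hour_window[2]
  if (!any(sel)) stop("hour window contains no session hours")
  if (any(bins$phase[sel] != "reversal")) {
    stop("extinction window must lie within the reversal phase")
  }
  b <- bins[sel, , drop = FALSE]
  pct <- function(n) ifelse(b$n_total > 0, 100 * n / b$n_total, NA_real_)
  out <- data.frame(
    animal_id = b$animal_id, hour = b$hour, n_total = b$n_total,
    pct_left = pct(b$n_left), pct_middle = pct(b$n_middle),
    pct_errors = pct(b$n_left + b$n_middle),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$animal_id, out$hour), , drop = FALSE]
}
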