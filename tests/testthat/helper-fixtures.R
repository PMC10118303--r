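# Shared fixture builders: events are constructed in code, never stored.

# Build an event data frame from session times (hours) and holes.
make_events <- function(t_hours, holes, animal_id = "m1") {
  data.frame(animal_id = rep_len(animal_id, length(t_hours)),
             t_seconds = t_hours * 3600,
             hole = holes, stringsAsFactors = FALSE)
}

# Events realizing a given correctness-flag sequence inside one phase:
# correct entries go to the phase's rewarded hole, errors to the middle.
events_from_flags <- function(flags, schedule, scope = "reversal",
                              animal_id = "m1") {
  start_h <- if (scope == "reversal") schedule$acquisition_hours else 0
  t_h <- start_h + seq_along(flags) / 360   # 10 s apart
  rewarded <- if (scope == "reversal") "right" else "left"
  wrong <- if (scope == "reversal") "left" else "right"
  make_events(t_h, ifelse(flags, rewarded, wrong), animal_id)
}

# Independent brute-force oracle: scan every full trailing window.
brute_force_criterion <- function(flags, window, threshold) {
  n <- length(flags)
  if (n < window) return(NA_integer_)
  for (i in window:n) {
    if (mean(flags[(i - window + 1):i]) >= threshold - 1e-12) return(i)
  }
  NA_integer_
}

# Small two-group criterion-result table for survival tests.
make_results <- function(etc, reached, ids = NULL) {
  n <- length(etc)
  data.frame(
    animal_id = ids %||% sprintf("m%02d", seq_len(n)),
    reached = reached, etc = etc, htc = etc / 100,
    errors_to_criterion = 0L, n_scope_entries = etc,
    censored = !reached, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
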