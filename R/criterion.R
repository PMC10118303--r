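#' Moving-window learning criterion
#'
#' @param window trailing window size in entries (default 30).
#' @param threshold required success fraction within the window (default 0.80,
#'   met with `>=`, so 24/30 meets an 80% criterion).
#' @param scope phase whose entries are scanned; the entry counter and the
#'   window are reset at scope start, so acquisition performance never carries
#'   into the reversal window.
#' @return An object of class `criterion_rule`.
#' @export
criterion_rule <- function(window = 30, threshold = 0.80,
                           scope = c("reversal", "acquisition")) {
  scope <- match.arg(scope)
  stopifnot(is.numeric(window), length(window) == 1L, window >= 1,
            window == as.integer(window),
            is.numeric(threshold), threshold > 0, threshold <= 1)
  structure(list(window = as.integer(window), threshold = threshold,
                 scope = scope),
            class = "criterion_rule")
}

#' Trailing-window success rate
#'
#' For a sequence of correct/incorrect flags, the success rate at entry `n`
#' (1-based) is the fraction of correct entries among entries
#' `n - window + 1 .. n`. The rate requires a full window: positions before
#' entry `window` are `NA`.
#'
#' @param correct logical vector of per-entry correctness flags.
#' @param window trailing window size in entries.
#' @return Numeric vector of the same length as `correct`.
#' @examples
#' trailing_success_rate(c(rep(FALSE, 6), rep(TRUE, 24)), 30)[30]  # 0.8
#' @export
trailing_success_rate <- function(correct, window) {
  stopifnot(is.numeric(window), length(window) == 1L, window >= 1)
  window <- as.integer(window)
  n <- length(correct)
  out <- rep(NA_real_, n)
  if (n >= window) {
    cs <- c(0, cumsum(as.integer(correct)))
    i <- window:n
    out[i] <- (cs[i + 1L] - cs[i - window + 1L]) / window
  }
  out
}

#' Detect criterion attainment for each animal
#'
#' Scans each animal's entries within the rule's scope phase for the first
#' entry at which the trailing-window success rate meets the threshold.
#' `etc` is the 1-based entry index within the scope at first attainment
#' (so the earliest possible value equals the window size); `htc` is the
#' session hour of the attaining entry. Animals that never attain are
#' censored: `etc` is their total scope entry count and `htc` the scope end
#' hour. An animal with zero scope entries is censored with `etc = 0`.
#'
#' @param events event data frame (one or many animals).
#' @param schedule a [session_schedule()].
#' @param rule a [criterion_rule()].
#' @return Data frame with one row per animal: `animal_id`, `reached`, `etc`,
#'   `htc`, `errors_to_criterion`, `n_scope_entries`, `censored`.
#' @export
detect_criterion <- function(events, schedule, rule = criterion_rule()) {
  stopifnot(inherits(schedule, "session_schedule"),
            inherits(rule, "criterion_rule"))
  t_h <- events$t_seconds / 3600
  ev <- events[phase_of(schedule, t_h) == rule$scope, , drop = FALSE]
  end_h <- scope_end_hour(schedule, rule$scope)
  ids <- unique(events$animal_id)
  chunks <- split(ev, factor(ev$animal_id, levels = ids))
  res <- lapply(ids, function(id) {
    e <- chunks[[id]]
    if (is.null(e) || nrow(e) == 0L) {
      return(data.frame(animal_id = id, reached = FALSE, etc = 0,
                        htc = end_h, errors_to_criterion = 0L,
                        n_scope_entries = 0L, censored = TRUE,
                        stringsAsFactors = FALSE))
    }
    e <- e[order(e$t_seconds), , drop = FALSE]
    corr <- e$hole == correct_hole(schedule, e$t_seconds / 3600)
    rate <- trailing_success_rate(corr, rule$window)
    hit <- which(!is.na(rate) & rate >= rule$threshold - 1e-12)
    if (length(hit)) {
      i <- hit[1L]
      data.frame(animal_id = id, reached = TRUE, etc = i,
                 htc = e$t_seconds[i] / 3600,
                 errors_to_criterion = sum(!corr[seq_len(i)]),
                 n_scope_entries = nrow(e), censored = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(animal_id = id, reached = FALSE, etc = nrow(e),
                 htc = end_h, errors_to_criterion = sum(!corr),
                 n_scope_entries = nrow(e), censored = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "rule") <- rule
  out
}

#' Criterion-attainment ("survival") table
#'
#' Step function of the proportion of animals having reached criterion as a
#' function of entries (ETC) or session hours (HTC), per group. Censored
#' animals are never counted as reached; they leave the risk set at their
#' censoring value. The curve is non-decreasing and ends at
#' (max observed value, fraction reached).
#'
#' @param results output of [detect_criterion()].
#' @param axis `"entries"` (ETC) or `"hours"` (HTC).
#' @param group optional group label per row of `results`; defaults to a
#'   `group` column if present, else a single pooled group.
#' @return Data frame with columns `axis`, `axis_value`, `group`, `n_at_risk`,
#'   `proportion_reached`.
#' @export
survival_table <- function(results, axis = c("entries", "hours"),
                           group = NULL) {
  axis <- match.arg(axis)
  stopifnot(nrow(results) >= 1L)
  val <- if (axis == "entries") results$etc else results$htc
  if (is.null(group)) {
    group <- if ("group" %in% names(results)) results$group else "all"
  }
  group <- rep_len(as.character(group), nrow(results))
  out <- lapply(unique(group), function(g) {
    sel <- group == g
    v <- val[sel]
    reached <- results$reached[sel]
    n <- sum(sel)
    steps <- sort(unique(v[reached]))
    vmax <- max(v)
    if (!length(steps) || steps[length(steps)] < vmax) {
      steps <- c(steps, vmax)
    }
    data.frame(
      axis = axis, axis_value = steps, group = g,
      n_at_risk = vapply(steps, function(s) sum(v >= s), integer(1)),
      proportion_reached = vapply(steps,
                                  function(s) sum(reached & v <= s) / n,
                                  numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
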