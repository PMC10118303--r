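#' Young-reference cutoff for cohort stratification
#'
#' Computes the operational cutoff that separates cognitively intact from
#' impaired aged animals, from the reversal entries-to-criterion (ETC) of a
#' young reference group. The default interpretation of the "90% confidence
#' interval" is the CI of the young mean: upper bound
#' `mean + t((1 + ci)/2, n - 1) * SEM`, then rounded up to the nearest 100
#' entries to give an operational threshold. With the young reference summary
#' mean 813.03, SEM 105.92, n 40 this yields a raw bound of about 991.5 and a
#' cutoff of 1,000 entries. A percentile reference-interval alternative is
#' selectable via `method = "percentile"` (requires raw values).
#'
#' @param values numeric vector of young reversal ETC values; may be omitted
#'   when `mean`, `sem` and `n` are supplied directly.
#' @param mean,sem,n summary statistics of the young reference (used when
#'   `values` is missing). `n` must be at least 2.
#' @param ci_level confidence level (default 0.90).
#' @param rounding `"ceil_to_100"` (default) rounds the raw bound up to the
#'   next multiple of 100 entries; `"none"` uses the raw bound.
#' @param method `"t_ci"` (default) for the CI-of-the-mean bound,
#'   `"percentile"` for the empirical upper percentile of `values`.
#' @return An object of class `reference_cutoff`: list with `metric`,
#'   `n_ref`, `mean_ref`, `sem_ref`, `ci_level`, `raw_upper_bound`, `cutoff`,
#'   `rounding`, `method`.
#' @examples
#' compute_reference_cutoff(mean = 813.03, sem = 105.92, n = 40)
#' @export
compute_reference_cutoff <- function(values = NULL, mean = NULL, sem = NULL,
                                     n = NULL, ci_level = 0.90,
                                     rounding = c("ceil_to_100", "none"),
                                     method = c("t_ci", "percentile")) {
  rounding <- match.arg(rounding)
  method <- match.arg(method)
  stopifnot(ci_level > 0, ci_level < 1)
  if (!is.null(values)) {
    values <- values[!is.na(values)]
    n <- length(values)
    if (n < 2L) stop("need at least 2 reference animals")
    mean <- base::mean(values)
    sem <- stats::sd(values) / sqrt(n)
  } else {
    if (is.null(mean) || is.null(sem) || is.null(n)) {
      stop("supply either raw values or all of mean, sem, n")
    }
    if (n < 2L) stop("need at least 2 reference animals")
    if (sem < 0) stop("sem must be non-negative")
    if (method == "percentile") {
      stop("percentile method requires raw values")
    }
  }
  raw <- if (method == "t_ci") {
    mean + stats::qt((1 + ci_level) / 2, df = n - 1) * sem
  } else {
    as.numeric(stats::quantile(values, probs = (1 + ci_level) / 2, type = 7))
  }
  cutoff <- switch(rounding,
                   ceil_to_100 = 100 * ceiling(raw / 100),
                   none = raw)
  structure(
    list(metric = "reversal_etc", n_ref = n, mean_ref = mean, sem_ref = sem,
         ci_level = ci_level, raw_upper_bound = raw, cutoff = cutoff,
         rounding = rounding, method = method),
    class = "reference_cutoff"
  )
}

#' @export
print.reference_cutoff <- function(x, ...) {
  cat(sprintf(
    "reference cutoff (%s): raw %g%% CI upper bound %.2f -> cutoff %g entries (%s, n_ref=%d)\n",
    x$metric, 100 * x$ci_level, x$raw_upper_bound, x$cutoff, x$rounding, x$n_ref
  ))
  invisible(x)
}

#' Classify ETC values against a cutoff
#'
#' An animal is `"intact"` when it reached criterion with ETC strictly below
#' the cutoff; ETC at or above the cutoff — or never reaching criterion
#' (censored) — is `"impaired"`. The boundary rule (ETC equal to the cutoff is
#' impaired) matches an "intact < cutoff" reading of the threshold.
#'
#' @param etc numeric vector of reversal ETC values.
#' @param cutoff a [compute_reference_cutoff()] object or a single number.
#' @param reached logical vector (default all `TRUE`): `FALSE` marks censored
#'   animals, classified impaired regardless of ETC.
#' @return Character vector of labels `"intact"` / `"impaired"`.
#' @export
classify_etc <- function(etc, cutoff, reached = TRUE) {
  cut_val <- if (inherits(cutoff, "reference_cutoff")) cutoff$cutoff else cutoff
  stopifnot(is.numeric(cut_val), length(cut_val) == 1L)
  reached <- rep_len(reached, length(etc))
  ifelse(reached & etc < cut_val, "intact", "impaired")
}

#' Stratify an aged cohort by reversal performance
#'
#' Applies [classify_etc()] to criterion results and summarizes each subgroup.
#' Classification is deterministic and order-independent.
#'
#' @param results output of [detect_criterion()] for the reversal phase.
#' @param cutoff a [compute_reference_cutoff()] object or a single number.
#' @return List with `labels` (data frame `animal_id`, `etc`, `censored`,
#'   `label`) and `summary` (per-label `n`, `mean_etc`, `sem_etc`), plus the
#'   `cutoff` used.
#' @export
classify_cohort <- function(results, cutoff) {
  if (nrow(results) == 0L) stop("empty cohort")
  lab <- classify_etc(results$etc, cutoff, reached = results$reached)
  labels <- data.frame(animal_id = results$animal_id, etc = results$etc,
                       censored = results$censored, label = lab,
                       stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(c("intact", "impaired"), function(g) {
    v <- labels$etc[labels$label == g]
    data.frame(label = g, n = length(v),
               mean_etc = if (length(v)) base::mean(v) else NA_real_,
               sem_etc = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                         else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(labels = labels, summary = summ,
       cutoff = if (inherits(cutoff, "reference_cutoff")) cutoff$cutoff
                else cutoff)
}

#' Z-scores of a per-animal metric
#'
#' Standardizes values to mean 0 and sample SD 1 (`n - 1` denominator) over a
#' reference set, by default the values themselves. `NA` inputs propagate and
#' are excluded from the reference mean/SD.
#'
#' @param values numeric vector.
#' @param reference optional numeric vector defining the standardization set
#'   (default `values`).
#' @return Numeric vector of z-scores.
#' @export
zscore_series <- function(values, reference = values) {
  ref <- reference[!is.na(reference)]
  if (length(ref) < 2L) stop("need at least 2 defined reference values")
  s <- stats::sd(ref)
  if (s == 0) stop("zero standard deviation in reference set")
  (values - base::mean(ref)) / s
}

#' Behavior-augmented 3D embedding
#'
#' Projects a samples-by-features matrix onto its top two principal
#' components (centered, optionally unit-scaled) and attaches a behavioral
#' z-score as the third coordinate. The sign of each component is fixed so
#' that its largest-magnitude loading is positive, making the embedding
#' reproducible across runs.
#'
#' @param x numeric matrix, rows are animals.
#' @param behavior_z numeric vector, one score per row of `x` (typically
#'   cognitive-flexibility z-scores from [zscore_series()]).
#' @param scale. logical, unit-scale features before decomposition
#'   (default `FALSE`).
#' @return Data frame of class `embedding3d` with columns `pc1`, `pc2`, `z3`;
#'   attribute `"explained_var"` holds the variance fractions of PC1/PC2.
#' @export
augment_embedding <- function(x, behavior_z, scale. = FALSE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3L, nrow(x) == length(behavior_z))
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  if (sum(pc$sdev > 1e-10 * pc$sdev[1]) < 2L) {
    stop("feature matrix has rank < 2 after centering")
  }
  scores <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  out <- data.frame(pc1 = unname(scores[, 1]), pc2 = unname(scores[, 2]),
                    z3 = behavior_z)
  if (!is.null(rownames(x))) out$animal_id <- rownames(x)
  ev <- pc$sdev^2
  attr(out, "explained_var") <- ev[1:2] / sum(ev)
  class(out) <- c("embedding3d", "data.frame")
  out
}
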