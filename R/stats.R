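#' Weighted log-rank family of survival comparisons
#'
#' Compares criterion-attainment distributions between k groups using the
#' weighted log-rank statistic over the pooled risk sets. `weights =
#' "logrank"` gives the standard log-rank test (weight 1 at every event
#' time); `weights = "gehan"` gives the Gehan-Breslow-Wilcoxon test (weight =
#' number at risk), which up-weights early differences. Censored subjects
#' contribute to risk sets until their censoring value. The statistic is
#' invariant to group order and to adding a constant to the time axis.
#'
#' @param time numeric event/censoring values (entries or hours).
#' @param event logical or 0/1: `TRUE` when criterion was reached (event),
#'   `FALSE` when censored.
#' @param group group label per subject (2 or more groups).
#' @param weights `"logrank"` or `"gehan"`.
#' @return Object of class `survival_comparison`: list with `chisq`, `df`,
#'   `p_value`, `weights`, `observed`, `expected`, `n` per group.
#' @export
weighted_logrank <- function(time, event, group,
                             weights = c("logrank", "gehan")) {
  weights <- match.arg(weights)
  group <- factor(group)
  event <- as.logical(event)
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) == 0L)) stop("a group has zero subjects")
  k <- nlevels(group)
  event_times <- sort(unique(time[event]))
  U <- numeric(k)
  V <- matrix(0, k, k)
  O <- numeric(k)
  E <- numeric(k)
  for (tj in event_times) {
    at_risk <- time >= tj
    n_j <- sum(at_risk)
    n_g <- tabulate(group[at_risk], nbins = k)
    d_g <- tabulate(group[event & time == tj], nbins = k)
    d_j <- sum(d_g)
    e_g <- d_j * n_g / n_j
    w <- if (weights == "gehan") n_j else 1
    U <- U + w * (d_g - e_g)
    O <- O + d_g
    E <- E + e_g
    if (n_j > 1L && d_j > 0L) {
      p <- n_g / n_j
      V <- V + w^2 * d_j * (n_j - d_j) / (n_j - 1) * (diag(p, k) - outer(p, p))
    }
  }
  u <- U[-k]
  v <- V[-k, -k, drop = FALSE]
  chisq <- tryCatch(
    drop(t(u) %*% solve(v, u)),
    error = function(e) drop(t(u) %*% pseudo_inverse(v) %*% u)
  )
  chisq <- max(chisq, 0)
  df <- k - 1L
  structure(
    list(chisq = chisq, df = df,
         p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
         weights = weights, observed = O, expected = E,
         n = as.integer(table(group)), groups = levels(group)),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  lab <- if (x$weights == "gehan") "Gehan-Wilcoxon" else "log-rank"
  cat(sprintf("%s test: chi-square %.3f, df %d, p = %.4g\n",
              lab, x$chisq, x$df, x$p_value))
  invisible(x)
}

#' @rdname weighted_logrank
#' @param results output of [detect_criterion()] with a group vector.
#' @param axis `"entries"` (ETC) or `"hours"` (HTC).
#' @export
logrank_test <- function(results, group, axis = c("entries", "hours")) {
  axis <- match.arg(axis)
  val <- if (axis == "entries") results$etc else results$htc
  weighted_logrank(val, results$reached, group, weights = "logrank")
}

#' @rdname weighted_logrank
#' @export
gehan_wilcoxon_test <- function(results, group,
                                axis = c("entries", "hours")) {
  axis <- match.arg(axis)
  val <- if (axis == "entries") results$etc else results$htc
  weighted_logrank(val, results$reached, group, weights = "gehan")
}

pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, .Machine$double.eps)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' One-way ANOVA on a grouped metric
#'
#' Thin wrapper around [stats::aov()] returning the classical decomposition.
#' Degenerate input with zero within-group variance but non-zero
#' between-group variance is reported as infinite F with p = 0 and
#' `degenerate = TRUE`.
#'
#' @param values numeric response.
#' @param group group label per value (2 or more groups, each with at least
#'   2 observations).
#' @return Object of class `anova_result`: list with `f`, `df_between`,
#'   `df_within`, `p_value`, `degenerate`, and the underlying `aov` fit
#'   (`NULL` in the degenerate case).
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  keep <- !is.na(values)
  values <- values[keep]
  group <- droplevels(group[keep])
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("each group needs at least 2 values")
  df_b <- nlevels(group) - 1L
  df_w <- length(values) - nlevels(group)
  ss_w <- sum(stats::ave(values, group, FUN = function(v) v - base::mean(v))^2)
  if (ss_w == 0) {
    grand <- base::mean(values)
    ss_b <- sum(tapply(values, group, length) *
                  (tapply(values, group, base::mean) - grand)^2)
    if (ss_b > 0) {
      return(structure(list(f = Inf, df_between = df_b, df_within = df_w,
                            p_value = 0, degenerate = TRUE, fit = NULL),
                       class = "anova_result"))
    }
  }
  fit <- stats::aov(values ~ group, data = data.frame(values, group))
  tab <- summary(fit)[[1]]
  structure(
    list(f = tab[["F value"]][1], df_between = tab[["Df"]][1],
         df_within = tab[["Df"]][2], p_value = tab[["Pr(>F)"]][1],
         degenerate = FALSE, fit = fit),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d) = %.3f, p = %.4g%s\n",
              x$df_between, x$df_within, x$f, x$p_value,
              if (x$degenerate) " (zero within-group variance)" else ""))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Wrapper around [stats::TukeyHSD()] on a [one_way_anova()] fit, returning a
#' tidy table of pairwise differences with studentized-range adjusted
#' p-values.
#'
#' @param anova an `anova_result` from [one_way_anova()].
#' @return Data frame: `comparison`, `diff`, `lwr`, `upr`, `p_adjusted`.
#' @export
tukey_hsd <- function(anova) {
  stopifnot(inherits(anova, "anova_result"))
  if (is.null(anova$fit)) stop("Tukey HSD undefined for degenerate ANOVA")
  tk <- stats::TukeyHSD(anova$fit)$group
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adjusted = tk[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sidak multiple-comparison adjustment
#'
#' Adjusts p-values for `m` comparisons as `1 - (1 - p)^m`. The adjusted
#' value is never smaller than the raw value and is capped at 1.
#'
#' @param p numeric vector of raw p-values.
#' @param m number of comparisons (default `length(p)`).
#' @return Numeric vector of adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' OXPHOS coupling efficiency
#'
#' Efficiency of ATP-coupled respiration from high-resolution respirometry
#' states: `1 - GM/S`, where GM is the oxygen consumption rate in the
#' glutamate/malate (complex I, leak-dominated) state and S the rate in the
#' succinate-supported state, both after subtracting the non-mitochondrial
#' (antimycin-A) baseline. Values are in matched units (e.g. pmol O2 s^-1
#' mg^-1). A GM rate exceeding S yields a negative efficiency which is
#' reported with a warning, never silently clamped.
#'
#' @param ocr_gm oxygen consumption rate in the glutamate/malate state.
#' @param ocr_s oxygen consumption rate in the succinate state.
#' @param baseline antimycin-A rate subtracted from both (default 0).
#' @return Numeric vector of efficiencies.
#' @examples
#' coupling_efficiency(30, 120)  # 0.75
#' @export
coupling_efficiency <- function(ocr_gm, ocr_s, baseline = 0) {
  gm <- ocr_gm - baseline
  s <- ocr_s - baseline
  if (any(gm < 0)) stop("negative glutamate/malate rate after baseline subtraction")
  if (any(s <= 0)) stop("succinate-state rate must be positive after baseline subtraction")
  eff <- 1 - gm / s
  if (any(eff < 0)) {
    warning("GM rate exceeds succinate rate: negative coupling efficiency reported")
  }
  eff
}
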