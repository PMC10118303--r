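test_that("weighted log-rank matches hand-tabulated risk-set arithmetic", {
  # A events at 1, 3; B events at 2, 4; no censoring.
  # log-rank: U_A = 1/2 - 1/3 + 1/2 = 2/3, V = 1/4 + 2/9 + 1/4 = 13/18
  #   -> chi-square = (2/3)^2 / (13/18) = 8/13
  # Gehan:   U_A = 4/2 - 3/3 + 2/2 = 2,  V = 4 + 2 + 1 = 7 -> 4/7
  time <- c(1, 3, 2, 4)
  grp <- c("A", "A", "B", "B")
  lr <- weighted_logrank(time, rep(TRUE, 4), grp, "logrank")
  gw <- weighted_logrank(time, rep(TRUE, 4), grp, "gehan")
  expect_equal(lr$chisq, 8 / 13)
  expect_equal(gw$chisq, 4 / 7)
  expect_equal(lr$df, 1L)
})

test_that("log-rank agrees with survival::survdiff and is invariant to relabeling/shift", {
  skip_if_not_installed("survival")
  set.seed(12)
  n <- 60
  time <- c(rexp(n / 2, 1), rexp(n / 2, 1.8))
  event <- runif(n) > 0.2
  grp <- rep(c("g1", "g2"), each = n / 2)
  lr <- weighted_logrank(time, event, grp, "logrank")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(lr$chisq, sd_fit$chisq, tolerance = 1e-10)

  # three groups too
  grp3 <- rep(c("a", "b", "c"), each = n / 3)
  lr3 <- weighted_logrank(time, event, grp3, "logrank")
  sd3 <- survival::survdiff(survival::Surv(time, event) ~ grp3)
  expect_equal(lr3$chisq, sd3$chisq, tolerance = 1e-10)
  expect_equal(lr3$df, 2L)

  # invariance: group order and time origin
  perm <- sample(n)
  lr_p <- weighted_logrank(time[perm], event[perm], grp[perm], "logrank")
  expect_equal(lr_p$chisq, lr$chisq)
  lr_s <- weighted_logrank(time + 100, event, grp, "logrank")
  expect_equal(lr_s$chisq, lr$chisq)
  gw <- weighted_logrank(time, event, grp, "gehan")
  gw_s <- weighted_logrank(time + 100, event, grp, "gehan")
  expect_equal(gw_s$chisq, gw$chisq)
})

test_that("identical groups give a null statistic; early separation favors Gehan", {
  v <- c(30, 50, 70, 90, 120, 150)
  res <- make_results(rep(v, 2), rep(TRUE, 12))
  grp <- rep(c("A", "B"), each = 6)
  lr <- logrank_test(res, grp)
  gw <- gehan_wilcoxon_test(res, grp)
  expect_lt(lr$chisq, 1e-10)
  expect_lt(gw$chisq, 1e-10)
  expect_gt(lr$p_value, 0.99)

  # early difference, late convergence: Gehan's n-at-risk weights make it
  # more sensitive than the log-rank
  early_a <- c(10, 15, 20, 25, 200, 210, 220, 230)
  early_b <- c(60, 70, 80, 90, 201, 211, 221, 231)
  res2 <- make_results(c(early_a, early_b), rep(TRUE, 16))
  grp2 <- rep(c("A", "B"), each = 8)
  lr2 <- logrank_test(res2, grp2)
  gw2 <- gehan_wilcoxon_test(res2, grp2)
  expect_gt(gw2$chisq, lr2$chisq)

  expect_error(weighted_logrank(1:4, rep(TRUE, 4), rep("A", 4)), "2 groups")
})

test_that("log-rank and Gehan p-values sit inside their permutation-null intervals", {
  set.seed(2024)
  n <- 20
  time <- c(rexp(10, 1), rexp(10, 2.2))
  event <- rep(TRUE, n)
  event[c(4, 17)] <- FALSE
  grp <- rep(c("A", "B"), each = 10)
  B <- 10000
  for (w in c("logrank", "gehan")) {
    obs <- weighted_logrank(time, event, grp, w)
    perm <- replicate(B, {
      g <- sample(grp)
      weighted_logrank(time, event, g, w)$chisq
    })
    p_perm <- (1 + sum(perm >= obs$chisq - 1e-12)) / (B + 1)
    mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / B)
    # asymptotic p agrees with the exact permutation null within Monte-Carlo
    # error plus a small-sample approximation allowance
    expect_lt(abs(obs$p_value - p_perm), mc_err + 0.02)
  }
})

test_that("one-way ANOVA matches brute-force sums of squares and handles degeneracy", {
  expect_equal(one_way_anova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))$f, 0)
  expect_equal(one_way_anova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))$p_value, 1)

  set.seed(6)
  vals <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 3))
  grp <- rep(c("y", "i", "m"), each = 8)
  a <- one_way_anova(vals, grp)
  # independent arithmetic oracle
  grand <- mean(vals)
  ss_b <- sum(tapply(vals, grp, length) * (tapply(vals, grp, mean) - grand)^2)
  ss_w <- sum((vals - ave(vals, grp))^2)
  f_oracle <- (ss_b / 2) / (ss_w / 21)
  expect_equal(a$f, f_oracle, tolerance = 1e-10)
  expect_equal(a$p_value, pf(f_oracle, 2, 21, lower.tail = FALSE),
               tolerance = 1e-10)

  sep <- one_way_anova(c(0, 0, 0, 10, 10, 10) + rnorm(6, 0, 1e-4),
                       rep(c("a", "b"), each = 3))
  expect_lt(sep$p_value, 1e-6)

  deg <- one_way_anova(c(0, 0, 0, 10, 10, 10), rep(c("a", "b"), each = 3))
  expect_true(deg$degenerate)
  expect_equal(deg$f, Inf)
  expect_equal(deg$p_value, 0)
})

test_that("Tukey for two groups collapses to the t-test; Sidak never lowers p", {
  set.seed(13)
  vals <- c(rnorm(10, 0), rnorm(10, 0.9))
  grp <- rep(c("a", "b"), each = 10)
  a <- one_way_anova(vals, grp)
  tk <- tukey_hsd(a)
  tt <- t.test(vals ~ grp, var.equal = TRUE)
  expect_equal(tk$p_adjusted, tt$p.value, tolerance = 1e-8)

  p <- c(0.01, 0.04, 0.2, 0.9)
  adj <- sidak_adjust(p, m = 4)
  expect_true(all(adj >= p))
  expect_equal(adj, 1 - (1 - p)^4)
  expect_equal(sidak_adjust(0.9, m = 50), 1)
})

test_that("coupling efficiency follows 1 - GM/S with explicit degenerate handling", {
  expect_equal(coupling_efficiency(100, 100), 0)
  expect_equal(coupling_efficiency(0, 50), 1)
  expect_equal(coupling_efficiency(30, 120), 0.75)
  # antimycin-A baseline subtracted from both states
  expect_equal(coupling_efficiency(40, 130, baseline = 10), 0.75)
  expect_error(coupling_efficiency(10, 0), "positive")
  expect_warning(eff <- coupling_efficiency(120, 100), "negative")
  expect_equal(eff, 1 - 1.2)
})
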