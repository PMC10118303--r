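test_that("reference cutoff reproduces the operational 1,000-entry threshold", {
  ref <- compute_reference_cutoff(mean = 813.03, sem = 105.92, n = 40)
  # frozen value computed independently: 813.03 + t(0.95, 39) * 105.92
  expect_equal(ref$raw_upper_bound, 991.492, tolerance = 1e-3)
  expect_equal(ref$cutoff, 1000)
  expect_true(ref$cutoff >= ref$raw_upper_bound)

  # degenerate: SEM = 0 collapses the bound onto the mean
  ref0 <- compute_reference_cutoff(mean = 750, sem = 0, n = 10)
  expect_equal(ref0$raw_upper_bound, 750)
  expect_equal(ref0$cutoff, 800)

  # raw-values route agrees with the summary route
  set.seed(21)
  vals <- rnorm(40, 813, 600)
  ref_v <- compute_reference_cutoff(values = vals)
  ref_s <- compute_reference_cutoff(mean = mean(vals),
                                    sem = sd(vals) / sqrt(40), n = 40)
  expect_equal(ref_v$raw_upper_bound, ref_s$raw_upper_bound)

  expect_error(compute_reference_cutoff(values = 500), "at least 2")
})

test_that("classification applies the intact-below-cutoff rule with censoring", {
  ref <- compute_reference_cutoff(mean = 813.03, sem = 105.92, n = 40)
  expect_equal(classify_etc(c(736.81, 2439.05), ref), c("intact", "impaired"))
  # boundary tie goes to impaired ("intact < 1,000 entries")
  expect_equal(classify_etc(1000, ref), "impaired")
  expect_equal(classify_etc(999.99, ref), "intact")
  # censored animals are impaired regardless of their entry count
  expect_equal(classify_etc(500, ref, reached = FALSE), "impaired")

  res <- make_results(c(700, 800, 1500, 2500, 900), rep(TRUE, 5))
  cls <- classify_cohort(res, ref)
  expect_equal(sum(cls$labels$label == "intact"), 3L)
  expect_equal(cls$summary$n, c(3L, 2L))
  expect_equal(cls$summary$mean_etc[1], mean(c(700, 800, 900)))
  # order independence
  cls_rev <- classify_cohort(res[5:1, ], ref)
  expect_equal(sort(paste(cls$labels$animal_id, cls$labels$label)),
               sort(paste(cls_rev$labels$animal_id, cls_rev$labels$label)))
  expect_error(classify_cohort(res[0, ], ref), "empty")
})

test_that("z-scores use the sample-SD convention and standardize exactly", {
  expect_equal(zscore_series(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  v <- rnorm(25, 10, 4)
  z <- zscore_series(v)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_error(zscore_series(rep(5, 10)), "zero standard deviation")
  # NA propagates without poisoning the reference
  z2 <- zscore_series(c(v, NA))
  expect_true(is.na(z2[26]))
  expect_equal(z2[1:25], z)
})

test_that("behavior-augmented embedding recovers planted structure", {
  set.seed(17)
  n_per <- 8
  groups <- rep(c("young", "aged_intact", "aged_impaired"), each = n_per)
  cohort <- data.frame(animal_id = sprintf("m%02d", seq_along(groups)),
                       group = groups, stringsAsFactors = FALSE)
  x <- generate_feature_matrix(cohort, n_features = 60, effect_size = 6,
                               seed = 33)
  z <- zscore_series(rnorm(nrow(x)))
  emb <- augment_embedding(x, z)
  expect_equal(nrow(emb), nrow(x))
  expect_equal(emb$z3, z)
  expect_equal(mean(emb$pc1), 0, tolerance = 1e-8)
  expect_equal(mean(emb$pc2), 0, tolerance = 1e-8)

  # construct a matrix with two known orthogonal shift directions and little
  # noise: the fitted PC1/PC2 plane recovers the planted subspace
  d1 <- c(rep(1, 10), rep(0, 30)) / sqrt(10)
  d2 <- c(rep(0, 10), rep(1, 10), rep(0, 20)) / sqrt(10)
  a <- rep(c(-4, 4, 0), each = n_per)
  b <- rep(c(0, -4, 4), each = n_per)
  xk <- outer(a, d1) + outer(b, d2) +
    matrix(rnorm(length(groups) * 40, sd = 0.05), nrow = length(groups))
  fitted <- prcomp(xk, center = TRUE)$rotation[, 1:2]
  planted <- cbind(d1, d2)
  angles <- acos(pmin(1, svd(t(planted) %*% fitted)$d)) * 180 / pi
  expect_true(all(angles < 5))

  # centroid separation exceeds within-group spread in the 3D coordinates
  flex_z <- zscore_series(ifelse(grepl("impaired", groups), -1, 1) + rnorm(24, 0, 0.2))
  emb2 <- augment_embedding(x, flex_z)
  coords <- as.matrix(emb2[, c("pc1", "pc2", "z3")])
  cent <- apply(coords, 2, function(cc) tapply(cc, groups, mean))
  d_between <- min(dist(cent))
  r_within <- mean(sqrt(rowSums((coords - cent[groups, ])^2)))
  expect_true(d_between > r_within)

  # duplicated rows map to identical coordinates
  x_dup <- rbind(x, x)
  emb_dup <- augment_embedding(x_dup, c(z, z))
  expect_equal(emb_dup$pc1[1:24], emb_dup$pc1[25:48])
  expect_error(augment_embedding(matrix(1, 5, 4), rep(0, 5)), "rank")
})
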