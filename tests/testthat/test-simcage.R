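sched <- session_schedule()

test_that("entry streams are deterministic in (profile, schedule, seed)", {
  p <- default_profiles()$young
  e1 <- simulate_entry_stream(p, sched, seed = 31, animal_id = "a")
  e2 <- simulate_entry_stream(p, sched, seed = 31, animal_id = "a")
  expect_identical(e1, e2)
  e3 <- simulate_entry_stream(p, sched, seed = 32, animal_id = "a")
  expect_false(identical(e1$t_seconds, e3$t_seconds))
  expect_true(all(diff(e1$t_seconds) > 0))
  expect_true(all(e1$t_seconds >= 0 & e1$t_seconds <= 90 * 3600))
})

test_that("degenerate and frozen choice models produce their stated frequencies", {
  # q0 = q_asym = 1: every entry hits the currently correct hole
  perfect <- behavioral_profile("perfect", q0 = 1, q_asym = 1)
  ev <- simulate_entry_stream(perfect, sched, seed = 8, animal_id = "p")
  expect_true(all(ev$hole == correct_hole(sched, ev$t_seconds / 3600)))

  # tau_rev -> Inf with q0 = 1/3: reversal correct fraction stays at chance
  chance <- behavioral_profile("chance", q0 = 1 / 3, q_asym = 0.9,
                               tau_acq = 1e9, tau_rev = 1e9)
  ev2 <- simulate_entry_stream(chance, sched, seed = 9, animal_id = "c")
  rev <- ev2[ev2$t_seconds / 3600 >= 49, ]
  expect_gt(nrow(rev), 3000)
  expect_lt(abs(mean(rev$hole == "right") - 1 / 3), 0.03)

  # frozen constant-p model: chi-square goodness of fit on hole frequencies
  frozen <- behavioral_profile("frozen", q0 = 0.6, q_asym = 0.6,
                               w_persev = 0.65, beta_mid = 0.5)
  ev3 <- simulate_entry_stream(frozen, sched, seed = 10, animal_id = "f")
  rev3 <- ev3[ev3$t_seconds / 3600 >= 49, ]
  counts <- table(factor(rev3$hole, c("left", "middle", "right")))
  # reversal: correct (right) 0.6; errors split 0.65 left / 0.35 middle
  gof <- chisq.test(counts, p = c(0.65 * 0.4, 0.35 * 0.4, 0.6))
  expect_gt(gof$p.value, 0.001)
})

test_that("cohort simulation conserves counts, derives per-animal seeds and reproduces", {
  prof <- default_profiles()
  cfg <- simulation_config(
    profiles = list(young = list(profile = prof$young, n = 3),
                    aged_impaired = list(profile = prof$aged_impaired, n = 3)),
    seed = 77
  )
  sim <- simulate_cohort(cfg)
  expect_equal(length(unique(sim$events$animal_id)), 6L)
  expect_equal(nrow(sim$cohort), 6L)
  expect_equal(length(unique(sim$activity$animal_id)), 6L)
  expect_equal(nrow(sim$activity), 6L * 90L)
  expect_true(all(sim$activity$distance_cm >= 0))
  expect_true(all(sim$activity$pellets >= 0))
  expect_equal(sim$cohort$group, rep(c("young", "aged_impaired"), each = 3))

  sim2 <- simulate_cohort(cfg)
  expect_identical(sim, sim2)

  # different animals get different streams
  e_by <- split(sim$events$t_seconds, sim$events$animal_id)
  expect_false(identical(e_by[[1]], e_by[[2]]))

  dup_cfg <- cfg
  names(dup_cfg$profiles) <- c("young", "young")
  expect_error(simulate_cohort(dup_cfg), "duplicate")
})

test_that("entry counts scale with the dark/light rates", {
  p <- behavioral_profile("r", rate_dark = 120, rate_light = 25)
  ev <- simulate_entry_stream(p, sched, seed = 14, animal_id = "r")
  hr <- floor(ev$t_seconds / 3600)
  dark <- is_dark_hour(sched, hr)
  per_dark <- sum(dark) / sum(is_dark_hour(sched, 0:89))
  per_light <- sum(!dark) / sum(!is_dark_hour(sched, 0:89))
  expect_equal(per_dark / per_light, 120 / 25, tolerance = 0.15)
})

test_that("activity traces do not differ across groups", {
  prof <- default_profiles()
  sig <- 0L
  for (s in 1:20) {
    cfg <- simulation_config(
      profiles = lapply(prof, function(p) list(profile = p, n = 16)),
      seed = 1000 + s
    )
    sim <- simulate_cohort(cfg)
    tot <- tapply(sim$activity$distance_cm, sim$activity$animal_id, mean)
    grp <- sim$cohort$group[match(names(tot), sim$cohort$animal_id)]
    a <- one_way_anova(as.numeric(tot), grp)
    if (a$p_value < 0.05) sig <- sig + 1L
  }
  expect_lte(sig, 2L)
})

test_that("young animals almost always reach the acquisition criterion", {
  cfg <- simulation_config(
    profiles = list(young = list(profile = default_profiles()$young, n = 40)),
    seed = 555
  )
  sim <- simulate_cohort(cfg)
  res <- detect_criterion(sim$events, sched, criterion_rule(scope = "acquisition"))
  expect_gte(mean(res$reached), 0.95)
})

test_that("feature matrix carries the requested group structure", {
  groups <- rep(c("young", "aged_intact", "aged_impaired"), each = 10)
  cohort <- data.frame(animal_id = sprintf("m%02d", 1:30), group = groups,
                       stringsAsFactors = FALSE)
  x0 <- generate_feature_matrix(cohort, n_features = 40, effect_size = 0,
                                seed = 3)
  # null case: no feature separates the groups beyond chance
  p_null <- apply(x0, 2, function(v) one_way_anova(v, groups)$p_value)
  expect_gt(min(p_null), 0.05 / 40 / 10)   # no overwhelming signal
  expect_gt(mean(p_null > 0.05), 0.8)

  x5 <- generate_feature_matrix(cohort, n_features = 40, effect_size = 6,
                                seed = 3)
  pc1 <- prcomp(x5, center = TRUE)$x[, 1]
  aged <- grepl("aged", groups)
  # first principal component separates aged from young with zero overlap
  expect_true(max(pc1[!aged]) < min(pc1[aged]) ||
              min(pc1[!aged]) > max(pc1[aged]))

  expect_identical(x5, generate_feature_matrix(cohort, 40, 6, seed = 3))
  expect_false(identical(x5, generate_feature_matrix(cohort, 40, 6, seed = 4)))
})
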