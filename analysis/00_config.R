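# Shared study configuration for the analysis scripts.
#
# The simulated study mirrors the reference cohort layout: 40 young animals
# (the reference group), and an aged cohort whose generative composition is
# 16 intact-phenotype and 19 impaired-phenotype animals. One master seed
# drives everything; each script re-derives the cohort deterministically.

library(phenostrat)

MASTER_SEED <- 20230327
SCHED <- session_schedule()

study_config <- function(seed = MASTER_SEED) {
  prof <- default_profiles()
  simulation_config(
    profiles = list(
      young = list(profile = prof$young, n = 40),
      aged_intact = list(profile = prof$aged_intact, n = 16),
      aged_impaired = list(profile = prof$aged_impaired, n = 19)
    ),
    schedule = SCHED,
    seed = seed
  )
}

study_cohort <- function(seed = MASTER_SEED) simulate_cohort(study_config(seed))

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}

write_result <- function(df, name) {
  path <- file.path(results_dir(), name)
  utils::write.csv(df, path, row.names = FALSE)
  message("  wrote ", path, " (", nrow(df), " rows)")
  invisible(path)
}
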