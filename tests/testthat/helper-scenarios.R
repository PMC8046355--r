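# Shared scenario runs for the acceptance suite: each named configuration
# is simulated and scored once and reused across test blocks.

.scenario_cache <- new.env(parent = emptyenv())

scenario_result <- function(name) {
  if (!is.null(.scenario_cache[[name]])) {
    return(.scenario_cache[[name]])
  }
  cfg <- switch(name,
    ideal = scenario_config(),
    ideal_small = scenario_config(n_preys = 5000),
    replicates2 = scenario_config(n_replicates = 2),
    replicates5 = scenario_config(n_replicates = 5),
    baits2 = scenario_config(n_baits = 2),
    low_concentration = scenario_config(low_concentration = TRUE),
    stop("unknown scenario: ", name)
  )
  res <- glance(run_scenario(cfg, seeds = 1:3))
  .scenario_cache[[name]] <- res
  res
}

auc_mean <- function(res, score, metric) {
  res[[metric]][res$score == score]
}
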