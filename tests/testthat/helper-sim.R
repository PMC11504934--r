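# Shared simulation fixtures. Mid-sized pipeline runs are cached per session
# so several test files can reuse one generator -> prep -> screen -> score
# chain without re-paying the imputation cost.

.fixture_env <- new.env(parent = emptyenv())

# A compact cohort that still exercises every pipeline feature: rare
# binaries, a planted collinear pair, MAR missingness, subgroup shifts.
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_families = 420, mean_children_per_family = 1.2,
                   n_exposures = 12, n_true_risk = 4, n_true_protective = 1,
                   n_rare = 1, n_collinear_pairs = 1,
                   missing_rate = 0.10, seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# No-missingness, no-rare, no-collinear config for model-focused tests.
clean_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_families = 420, mean_children_per_family = 1.2,
                   n_exposures = 6, n_true_risk = 2, n_true_protective = 1,
                   n_rare = 0, n_collinear_pairs = 0,
                   missing_rate = 0, seed = 202L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Mid-sized end-to-end run shared across test files (~2,900 children).
pipeline_fixture <- function() {
  if (!is.null(.fixture_env$pipeline)) return(.fixture_env$pipeline)
  cfg <- sim_config(n_families = 2400, mean_children_per_family = 1.2,
                    n_exposures = 20, n_true_risk = 6, n_true_protective = 1,
                    n_rare = 2, n_collinear_pairs = 2,
                    missing_rate = 0.10, seed = 424L)
  sim <- simulate_cohort(cfg)
  specs <- exposure_specs(sim$truth)
  prep <- suppressWarnings(run_prep(sim$cohort, specs, n_trees = 15,
                                    max_iter = 4, seed = 7))
  exwas <- run_exwas(prep$cohort, prep$specs$name, specs = prep$specs)
  scores <- compute_scores(prep$cohort, exwas)
  .fixture_env$pipeline <- list(cfg = cfg, sim = sim, specs = specs,
                                prep = prep, exwas = exwas, scores = scores)
  .fixture_env$pipeline
}
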