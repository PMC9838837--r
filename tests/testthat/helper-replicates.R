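# Shared replicate runner for the simulation-based checks. Results are
# cached per argument set so different test files can reuse the same
# (expensive) replicate sets within one test run.

.replicate_cache <- new.env(parent = emptyenv())

# Run n_reps independent (draw, configure both arms, evaluate scenarios)
# replicates and return one tidy row per scenario per replicate.
run_scenario_reps <- function(spec, n, n_reps, n_candidates,
                              master_seed = 20260926, label = "cell") {
  key <- rlang::hash(list(spec_hash = svyboost:::spec_hash(spec), n = n,
                          n_reps = n_reps, n_candidates = n_candidates,
                          master_seed = master_seed, label = label))
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  grid <- experiment_grid(
    sample_sizes = n,
    conditions = tibble::tibble(condition = label, axis = NA_character_,
                                value = NA_real_),
    n_replicates = n_reps,
    n_candidates = n_candidates,
    n_boot = 100,
    master_seed = master_seed
  )
  rows <- dplyr::bind_rows(lapply(seq_len(n_reps), function(r) {
    run_cell(spec, n, grid, replicate = r, condition = label)
  }))
  .replicate_cache[[key]] <- rows
  rows
}

mean_abs_error <- function(rows, scen) {
  mean(abs(rows$error_vs_gold[rows$scenario == scen]))
}
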