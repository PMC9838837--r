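#' Error of a scenario F1 relative to the gold standard
#'
#' Returns `(f1_scenario - f1_gold) * 100` in percentage points, computed
#' from unrounded F1 fractions (rounding only ever happens in display).
#'
#' @param f1_scenario,f1_gold F1 fractions in \[0, 1\].
#' @return Signed percentage points.
#' @export
#' @examples
#' error_vs_gold(0.819, 0.774) # +4.5
error_vs_gold <- function(f1_scenario, f1_gold) {
  stopifnot(f1_scenario >= 0, f1_scenario <= 1, f1_gold >= 0, f1_gold <= 1)
  (f1_scenario - f1_gold) * 100
}

#' Evaluate the three survey-weighting scenarios
#'
#' Compares three analytic scenarios on one dataset:
#' * **Scenario One** (gold standard): survey-weighted F1 of the
#'   weight-aware configuration's out-of-fold predictions — a model aware of
#'   the weights, scored against the weighted (population) outcome
#'   distribution.
#' * **Scenario Two** (naive): unweighted F1 of the unweighted
#'   configuration's predictions — weights ignored everywhere.
#' * **Scenario Three** (post-hoc rescue): survey-weighted F1 of the
#'   unweighted configuration's predictions — a weight-naive model rescored
#'   in weighted data, as when a model is deployed in a representative
#'   sample.
#'
#' Each F1 gets a percentile bootstrap CI (observation-level resampling,
#' shared resample seed across scenarios so comparisons are paired) and a
#' signed error in percentage points against Scenario One.
#'
#' @param weighted_cfg,unweighted_cfg `fitted_configuration`s built on the
#'   same dataset (hash-checked) with and without weights.
#' @param threshold Classification cutoff.
#' @param n_boot Bootstrap resamples per scenario.
#' @param alpha CI miscoverage.
#' @param seed Integer seed for the bootstrap.
#' @return A `scenario_eval` tibble with one row per scenario: `scenario`,
#'   `configuration`, `evaluation`, `f1`, `ci_low`, `ci_high`,
#'   `error_vs_gold`.
#' @export
#' @examples
#' \donttest{
#' spec <- baseline_population(1)
#' d <- draw_survey_sample(spec, 500, seed = 2)
#' cw <- configure_model(d, TRUE, n_candidates = 2, seed = 3)
#' cu <- configure_model(d, FALSE, n_candidates = 2, seed = 3)
#' evaluate_scenarios(cw, cu, n_boot = 200, seed = 4)
#' }
evaluate_scenarios <- function(weighted_cfg, unweighted_cfg,
                               threshold = 0.5, n_boot = 1000,
                               alpha = 0.05, seed = 1) {
  stopifnot(inherits(weighted_cfg, "fitted_configuration"),
            inherits(unweighted_cfg, "fitted_configuration"),
            weighted_cfg$weighted_training,
            !unweighted_cfg$weighted_training)
  if (!identical(weighted_cfg$data_hash, unweighted_cfg$data_hash))
    abort("the two configurations were not built from the same dataset")
  boot_seed <- derive_seed(seed, "scenario-bootstrap")
  scen <- function(preds, weighted) {
    bootstrap_metric(preds, weighted = weighted, metric = "f1",
                     threshold = threshold, n_boot = n_boot, alpha = alpha,
                     seed = boot_seed)
  }
  s1 <- scen(weighted_cfg$oof, weighted = TRUE)
  s2 <- scen(unweighted_cfg$oof, weighted = FALSE)
  s3 <- scen(unweighted_cfg$oof, weighted = TRUE)
  out <- tibble::tibble(
    scenario = c("one", "two", "three"),
    configuration = c("weighted", "unweighted", "unweighted"),
    evaluation = c("weighted", "unweighted", "weighted"),
    f1 = c(s1$estimate, s2$estimate, s3$estimate),
    ci_low = c(s1$ci_low, s2$ci_low, s3$ci_low),
    ci_high = c(s1$ci_high, s2$ci_high, s3$ci_high),
    n_boot = as.integer(n_boot)
  )
  out$error_vs_gold <- c(0, error_vs_gold(s2$estimate, s1$estimate),
                         error_vs_gold(s3$estimate, s1$estimate))
  attr(out, "data_hash") <- weighted_cfg$data_hash
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("scenario_eval", class(out))
  out
}
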