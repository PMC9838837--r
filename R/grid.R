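#' Define a simulation experiment grid
#'
#' Describes the full simulation design: sample sizes crossed with
#' modification conditions, each replicated `n_replicates` times, with a
#' randomized hyperparameter search of `n_candidates` candidates per
#' weighted/unweighted arm. The default conditions reproduce the study's
#' seven arms: baseline, predictor coefficients doubled and halved,
#' weight variance doubled and halved, dimensionality reduced to 10
#' informative predictors, and the all-null sensitivity arm.
#'
#' Every cell's seed derives from `(master_seed, condition, n, replicate)`
#' through a stable string hash, so results are independent of execution
#' order and of the number of parallel workers.
#'
#' @param sample_sizes Ascending vector of sample sizes.
#' @param conditions A tibble with columns `condition`, `axis`, `value`
#'   (axis `NA` means the unmodified baseline). Defaults to the seven
#'   study arms.
#' @param n_replicates Replicates per cell.
#' @param n_candidates Randomized-search candidates per configuration.
#' @param n_folds Cross-validation folds.
#' @param n_boot Bootstrap resamples per scenario F1.
#' @param master_seed Integer master seed.
#' @return An `experiment_grid` list.
#' @export
#' @examples
#' g <- experiment_grid(sample_sizes = c(250, 500), n_replicates = 2,
#'                      n_candidates = 3, master_seed = 1)
#' g$conditions
experiment_grid <- function(sample_sizes = c(250, 500, 2500, 5000, 10000),
                            conditions = default_conditions(),
                            n_replicates = 20,
                            n_candidates = 60,
                            n_folds = 5,
                            n_boot = 500,
                            master_seed = 1) {
  stopifnot(all(sample_sizes > 0), !is.unsorted(sample_sizes),
            n_replicates >= 1, n_candidates >= 1, n_folds >= 2)
  stopifnot(all(c("condition", "axis", "value") %in% names(conditions)))
  bad <- !is.na(conditions$axis) &
    !conditions$axis %in% c("beta_scale", "weight_variance", "dimensionality", "null")
  if (any(bad)) abort("unknown modification axis in conditions")
  structure(list(
    sample_sizes = sample_sizes,
    conditions = conditions,
    n_replicates = as.integer(n_replicates),
    n_candidates = as.integer(n_candidates),
    n_folds = as.integer(n_folds),
    n_boot = as.integer(n_boot),
    master_seed = as.integer(master_seed)
  ), class = "experiment_grid")
}

#' @rdname experiment_grid
#' @export
default_conditions <- function() {
  tibble::tribble(
    ~condition,                ~axis,             ~value,
    "baseline",                NA_character_,     NA_real_,
    "strong_predictors",       "beta_scale",      2,
    "weak_predictors",         "beta_scale",      0.5,
    "high_weight_variance",    "weight_variance", 2,
    "low_weight_variance",     "weight_variance", 0.5,
    "reduced_dimensionality",  "dimensionality",  10,
    "null",                    "null",            NA_real_
  )
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat("<experiment_grid>\n")
  cat(sprintf("  %d sizes x %d conditions x %d replicates (%d cells; %d result rows)\n",
              length(x$sample_sizes), nrow(x$conditions), x$n_replicates,
              length(x$sample_sizes) * nrow(x$conditions) * x$n_replicates,
              3L * length(x$sample_sizes) * nrow(x$conditions) * x$n_replicates))
  cat(sprintf("  search: %d candidates, %d folds; %d bootstrap resamples; master seed %d\n",
              x$n_candidates, x$n_folds, x$n_boot, x$master_seed))
  invisible(x)
}

# spec for one condition, built from the grid's baseline spec
condition_spec <- function(base_spec, axis, value) {
  if (is.na(axis)) return(base_spec)
  modify_population(base_spec, axis,
                    if (axis == "null") NULL else value)
}

#' Run one grid cell
#'
#' Draws one dataset, configures the weighted and unweighted models on
#' shared folds and candidates, evaluates the three scenarios, and returns
#' three tidy rows. The cell seed is derived from
#' `(master_seed, condition, n, replicate)`, so cells are reproducible in
#' isolation. Failures are captured as rows with `status = "failed"`.
#'
#' @param spec The (possibly modified) `population_spec` for the cell's
#'   condition.
#' @param n Sample size.
#' @param grid An `experiment_grid` (search settings, master seed).
#' @param replicate Replicate id (1-based).
#' @param condition Condition label used in seed derivation and output.
#' @return A tibble with three rows (one per scenario).
#' @export
run_cell <- function(spec, n, grid, replicate, condition = "baseline") {
  stopifnot(inherits(grid, "experiment_grid"))
  cell_seed <- derive_seed(grid$master_seed,
                           paste(condition, n, replicate, sep = "/"))
  base_row <- tibble::tibble(condition = condition, n = as.integer(n),
                             replicate = as.integer(replicate),
                             cell_seed = cell_seed)
  tryCatch({
    data <- draw_survey_sample(spec, n, seed = cell_seed)
    cfg_seed <- derive_seed(cell_seed, "configure")
    cfg_w <- configure_model(data, use_weights = TRUE,
                             n_candidates = grid$n_candidates,
                             n_folds = grid$n_folds, seed = cfg_seed)
    cfg_u <- configure_model(data, use_weights = FALSE,
                             n_candidates = grid$n_candidates,
                             n_folds = grid$n_folds, seed = cfg_seed)
    sc <- evaluate_scenarios(cfg_w, cfg_u, n_boot = grid$n_boot,
                             seed = derive_seed(cell_seed, "bootstrap"))
    dplyr::bind_cols(
      base_row[rep(1, 3), ],
      sc[c("scenario", "configuration", "evaluation", "f1",
           "ci_low", "ci_high", "error_vs_gold")],
      tibble::tibble(status = "ok", message = NA_character_)
    )
  }, error = function(e) {
    dplyr::bind_cols(
      base_row,
      tibble::tibble(scenario = NA_character_, configuration = NA_character_,
                     evaluation = NA_character_, f1 = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     error_vs_gold = NA_real_,
                     status = "failed", message = conditionMessage(e))
    )
  })
}

#' Run the full simulation grid
#'
#' Runs every (condition, sample size, replicate) cell, optionally across
#' parallel workers. Because each cell's seed derives from the master seed
#' and the cell's own coordinates, results are bitwise independent of the
#' worker count and of execution order. When `out_dir` is given, writes
#' `results.csv` (tidy rows), `summary.csv` (per condition x n x scenario
#' aggregates), `manifest.json` (seeds, settings, failed cells) and one
#' error-versus-sample-size figure per condition.
#'
#' @param grid An `experiment_grid`.
#' @param workers Parallel workers (forked; 1 = sequential).
#' @param out_dir Optional output directory.
#' @return A `grid_result` list: `results` (tibble), `summary` (tibble),
#'   `grid`. `autoplot()` draws the error-versus-sample-size panel.
#' @export
#' @examples
#' \donttest{
#' g <- experiment_grid(sample_sizes = c(250, 500),
#'                      conditions = default_conditions()[1, ],
#'                      n_replicates = 1, n_candidates = 2, n_boot = 200,
#'                      master_seed = 7)
#' res <- run_grid(g)
#' res$summary
#' }
run_grid <- function(grid, workers = 1, out_dir = NULL) {
  stopifnot(inherits(grid, "experiment_grid"))
  base_spec <- baseline_population(seed = derive_seed(grid$master_seed, "population"))
  specs <- lapply(seq_len(nrow(grid$conditions)), function(i) {
    condition_spec(base_spec, grid$conditions$axis[i], grid$conditions$value[i])
  })
  cells <- tidyr::expand_grid(
    cond_idx = seq_len(nrow(grid$conditions)),
    n = grid$sample_sizes,
    replicate = seq_len(grid$n_replicates)
  )
  one <- function(i) {
    ci <- cells$cond_idx[i]
    run_cell(specs[[ci]], cells$n[i], grid, cells$replicate[i],
             condition = grid$conditions$condition[ci])
  }
  rows <- if (workers > 1) {
    parallel::mclapply(seq_len(nrow(cells)), one, mc.cores = workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(seq_len(nrow(cells)), one)
  }
  results <- dplyr::bind_rows(rows)
  summary <- summarize_grid(results)
  out <- structure(list(results = results, summary = summary, grid = grid),
                   class = "grid_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(results, file.path(out_dir, "results.csv"))
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
    failed <- dplyr::filter(results, .data$status == "failed")
    manifest <- list(
      master_seed = grid$master_seed,
      sample_sizes = grid$sample_sizes,
      conditions = grid$conditions$condition,
      n_replicates = grid$n_replicates,
      n_candidates = grid$n_candidates,
      n_folds = grid$n_folds,
      n_boot = grid$n_boot,
      package_version = as.character(utils::packageVersion("svyboost")),
      n_failed_cells = nrow(failed),
      failed_cells = failed[c("condition", "n", "replicate", "message")]
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    for (cond in unique(results$condition)) {
      p <- plot_error_curves(results, conditions = cond)
      ggplot2::ggsave(file.path(out_dir, paste0("fig_", cond, ".png")),
                      p, width = 6, height = 4, dpi = 150)
    }
  }
  out
}

#' Aggregate grid results
#'
#' Mean F1, mean signed error, mean absolute error and replicate spread per
#' (condition, sample size, scenario).
#'
#' @param results A tidy results tibble from [run_grid()] (or `run_cell()`
#'   rows bound together).
#' @return A tibble with one row per condition x n x scenario.
#' @export
summarize_grid <- function(results) {
  results |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$condition, .data$n, .data$scenario) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_f1 = mean(.data$f1),
      mean_error = mean(.data$error_vs_gold),
      mean_abs_error = mean(abs(.data$error_vs_gold)),
      sd_error = stats::sd(.data$error_vs_gold),
      .groups = "drop"
    )
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result>\n")
  print(x$summary, n = 20)
  failed <- sum(x$results$status == "failed", na.rm = TRUE)
  if (failed > 0) cat(sprintf("  %d failed cell rows\n", failed))
  invisible(x)
}

#' Plot scenario error against sample size
#'
#' One line per scenario (Two and Three; Scenario One is the zero
#' reference) per condition, mirroring the study's error-by-sample-size
#' figures. Points are replicate means; ribbons span +/- one SD across
#' replicates.
#'
#' @param results A tidy results tibble from [run_grid()].
#' @param conditions Optional subset of condition labels to plot.
#' @return A ggplot object.
#' @export
plot_error_curves <- function(results, conditions = NULL) {
  agg <- summarize_grid(results) |>
    dplyr::filter(.data$scenario != "one")
  if (!is.null(conditions))
    agg <- dplyr::filter(agg, .data$condition %in% conditions)
  agg$scenario <- factor(agg$scenario, levels = c("two", "three"),
                         labels = c("Scenario Two (unweighted)",
                                    "Scenario Three (post-hoc weighted)"))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$n, y = .data$mean_error,
                                    colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_error - .data$sd_error,
                                      ymax = .data$mean_error + .data$sd_error,
                                      fill = .data$scenario),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "Sample size", y = "F1 error vs gold standard (pp)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' @rdname run_grid
#' @param object A `grid_result`.
#' @param ... Passed to [plot_error_curves()].
#' @export
autoplot.grid_result <- function(object, ...) {
  plot_error_curves(object$results, ...)
}
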