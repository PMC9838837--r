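#' Convert predicted probabilities to predicted classes
#'
#' @param p_hat Probabilities in \[0, 1\].
#' @param threshold Classification cutoff in (0, 1); the boundary is
#'   inclusive (`p_hat >= threshold` predicts 1).
#' @return An integer 0/1 vector.
#' @export
#' @examples
#' classify(c(0.2, 0.5, 0.8))
classify <- function(p_hat, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  as.integer(p_hat >= threshold)
}

#' Survey-weighted confusion cells
#'
#' Sums sampling weights (not counts) into the four confusion cells, so all
#' downstream metrics estimate population-level performance. With unit
#' weights the cells are the ordinary integer counts.
#'
#' @param y_obs Observed 0/1 outcomes.
#' @param y_pred Predicted 0/1 classes.
#' @param w Positive sampling weights (default all 1).
#' @return A `weighted_confusion` object with fields `tp`, `fp`, `fn`, `tn`;
#'   the cells always sum to `sum(w)`.
#' @export
#' @examples
#' weighted_confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), w = c(2, 1, 1, 3))
weighted_confusion <- function(y_obs, y_pred, w = rep(1, length(y_obs))) {
  if (length(y_obs) != length(y_pred) || length(y_obs) != length(w))
    abort("y_obs, y_pred and w must have equal length")
  if (any(w <= 0)) abort("weights must be positive")
  out <- list(
    tp = sum(w[y_obs == 1 & y_pred == 1]),
    fp = sum(w[y_obs == 0 & y_pred == 1]),
    fn = sum(w[y_obs == 1 & y_pred == 0]),
    tn = sum(w[y_obs == 0 & y_pred == 0])
  )
  structure(out, class = "weighted_confusion")
}

#' @export
print.weighted_confusion <- function(x, ...) {
  cat("<weighted_confusion>\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname weighted_confusion
#' @param x A `weighted_confusion`.
#' @param ... Unused.
#' @export
tidy.weighted_confusion <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "fn", "tn"),
                 weight = c(x$tp, x$fp, x$fn, x$tn))
}

#' Classification metrics from weighted confusion cells
#'
#' `sensitivity()` is tp/(tp+fn), `ppv()` is tp/(tp+fp), and `f1_score()` is
#' their harmonic mean, computed in the algebraically equivalent form
#' 2tp/(2tp+fp+fn). Degenerate cells (tp = 0 with positives present or
#' predicted, or no positives at all) return 0 by convention, with a
#' warning in the fully empty case, so simulation grids never abort.
#'
#' @param conf A `weighted_confusion`.
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' f1_score(weighted_confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), c(2, 1, 1, 3)))
f1_score <- function(conf) {
  stopifnot(inherits(conf, "weighted_confusion"))
  denom <- 2 * conf$tp + conf$fp + conf$fn
  if (denom == 0) {
    warn("no observed or predicted positives; F1 defined as 0")
    return(0)
  }
  2 * conf$tp / denom
}

#' @rdname f1_score
#' @export
sensitivity <- function(conf) {
  stopifnot(inherits(conf, "weighted_confusion"))
  if (conf$tp + conf$fn == 0) return(0)
  conf$tp / (conf$tp + conf$fn)
}

#' @rdname f1_score
#' @export
ppv <- function(conf) {
  stopifnot(inherits(conf, "weighted_confusion"))
  if (conf$tp + conf$fp == 0) return(0)
  conf$tp / (conf$tp + conf$fp)
}

#' Percentile bootstrap confidence interval for a prediction metric
#'
#' Resamples observation-level (y, p-hat, w) triples with replacement and
#' recomputes the metric on each resample, returning the full-sample point
#' estimate and the (alpha/2, 1-alpha/2) percentile interval using
#' linear-interpolation (type-7) quantiles. Resampling happens at the
#' predicted-probability level: models are never refit. Degenerate
#' resamples (a single class) contribute their defined-zero metric and are
#' counted in `n_degenerate`.
#'
#' @param preds A data frame with columns `y_obs`, `p_hat` and (if
#'   `weighted`) `w` — e.g. the `oof` element of a fitted configuration.
#' @param weighted If `TRUE` the metric sums sampling weights into the
#'   confusion cells; if `FALSE` all weights are 1.
#' @param metric Metric to bootstrap: `"f1"`, `"sensitivity"` or `"ppv"`.
#' @param threshold Classification cutoff.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param alpha Two-sided miscoverage (0.05 gives a 95% interval).
#' @param seed Integer seed.
#' @return A `metric_result`: list with `estimate`, `ci_low`, `ci_high`,
#'   `n_boot`, `alpha`, `n_degenerate`. Use `tidy()` for a one-row tibble.
#' @export
#' @examples
#' preds <- tibble::tibble(y_obs = rbinom(200, 1, 0.4),
#'                         p_hat = runif(200), w = rexp(200) + 0.1)
#' tidy(bootstrap_metric(preds, n_boot = 200, seed = 1))
bootstrap_metric <- function(preds, weighted = TRUE, metric = c("f1", "sensitivity", "ppv"),
                             threshold = 0.5, n_boot = 1000, alpha = 0.05, seed = 1) {
  metric <- match.arg(metric)
  stopifnot(n_boot >= 100, alpha > 0, alpha < 1)
  y <- preds$y_obs
  yp <- classify(preds$p_hat, threshold)
  w <- if (weighted) preds$w else rep(1, length(y))
  n <- length(y)
  # per-row weighted cell contributions; a resample's cells are subset sums
  w_tp <- w * (y == 1 & yp == 1)
  w_fp <- w * (y == 0 & yp == 1)
  w_fn <- w * (y == 1 & yp == 0)
  cell_metric <- function(tp, fp, fn, tn) {
    switch(metric,
      f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
      sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
      ppv = if (tp + fp == 0) 0 else tp / (tp + fp)
    )
  }
  estimate <- cell_metric(sum(w_tp), sum(w_fp), sum(w_fn), 0)
  n_degenerate <- 0L
  stats <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2L)
        n_degenerate <<- n_degenerate + 1L
      cell_metric(sum(w_tp[idx]), sum(w_fp[idx]), sum(w_fn[idx]), 0)
    }, numeric(1))
  })
  ci <- unname(stats::quantile(stats, c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), alpha = alpha,
                 n_degenerate = n_degenerate, metric = metric),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result> %s = %.4f [%.4f, %.4f] (%d bootstrap resamples, alpha = %s)\n",
              x$metric, x$estimate, x$ci_low, x$ci_high, x$n_boot,
              format(x$alpha)))
  invisible(x)
}

#' @rdname bootstrap_metric
#' @param x A `metric_result`.
#' @param ... Unused.
#' @export
tidy.metric_result <- function(x, ...) {
  tibble::tibble(metric = x$metric, estimate = x$estimate,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_boot = x$n_boot, alpha = x$alpha,
                 n_degenerate = x$n_degenerate)
}
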