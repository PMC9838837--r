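#' Simulate informative log-normal sampling weights
#'
#' Draws `n` log-normal weights whose arithmetic mean and standard deviation
#' match the requested targets exactly in expectation, using the closed-form
#' parameterization sigma^2 = log(1 + sd^2/mean^2),
#' mu = log(mean) - sigma^2/2. The draws are then reordered so their ranks
#' match the ranks of `rank_driver` (comonotone coupling, ties broken by row
#' index), which is how the generator makes weights informative: rows with a
#' larger driver (e.g. a larger inverse selection probability) always
#' receive the larger weights.
#'
#' @param n Number of weights.
#' @param mean Target arithmetic mean (> 0).
#' @param sd Target arithmetic standard deviation (>= 0); `sd = 0` returns
#'   `rep(mean, n)`.
#' @param rank_driver Numeric vector of length `n` scoring each row's
#'   informativeness; pass a constant (or `NULL`) for non-informative
#'   weights coupled only to row order.
#' @param seed Integer seed.
#' @return A positive numeric vector of length `n`.
#' @export
#' @examples
#' w <- simulate_weights(1000, mean = 9565, sd = 11820,
#'                       rank_driver = rep(1, 1000), seed = 1)
#' mean(w)
simulate_weights <- function(n, mean, sd, rank_driver = NULL, seed) {
  stopifnot(n >= 1, mean > 0)
  if (sd < 0) abort("sd must be nonnegative")
  rank_driver <- rank_driver %||% rep(0, n)
  stopifnot(length(rank_driver) == n)
  if (sd == 0) return(rep(mean, n))
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  draws <- withr::with_seed(seed, stats::rlnorm(n, mu, sqrt(sigma2)))
  sort(draws)[rank(rank_driver, ties.method = "first")]
}

#' Draw a synthetic complex-survey sample
#'
#' Draws `n` observations from the population described by `spec`:
#' (1) strata are assigned with probability proportional to frame share
#' times selection probability (sampling with replacement from an implicit
#' infinite frame); (2) predictors are generated from stratum-shifted
#' distributions; (3) the binary outcome is Bernoulli with probability
#' `expit(beta0 + X beta * beta_scale)`; (4) sampling weights are drawn by
#' [simulate_weights()] at the spec's weight mean and at SD
#' `weight_sd * sqrt(weight_variance_scale)`, rank-coupled to the base
#' design weights `1/selection_prob` so unequal selection stays encoded in
#' the final weights.
#'
#' If a class is absent the draw is retried with a derived seed, up to ten
#' times, before failing.
#'
#' @param spec A `population_spec`.
#' @param n Sample size (>= 50).
#' @param seed Integer seed; (spec, n, seed) fully determine the result.
#' @return A `survey_dataset`: a tibble with predictor columns `x1..xp`,
#'   `y` (0/1), `weight` (> 0) and `stratum`, carrying attributes
#'   `spec_hash`, `seed` and `predictor_info`.
#' @export
#' @examples
#' spec <- baseline_population(1)
#' d <- draw_survey_sample(spec, n = 500, seed = 42)
#' mean(d$y)
draw_survey_sample <- function(spec, n, seed) {
  stopifnot(inherits(spec, "population_spec"), n >= 50)
  samp_prob <- spec$frame_shares * spec$selection_probs
  samp_prob <- samp_prob / sum(samp_prob)
  attempt_seed <- as.integer(seed)
  for (attempt in seq_len(10L)) {
    dat <- withr::with_seed(attempt_seed, {
      stratum <- sample.int(spec$n_strata, n, replace = TRUE, prob = samp_prob)
      X <- draw_predictors(spec, n, stratum)
      pr <- expit(spec$beta0 + linear_predictor(spec, X) * spec$beta_scale)
      y <- stats::rbinom(n, 1L, pr)
      list(X = X, y = y, stratum = stratum)
    })
    if (length(unique(dat$y)) == 2L) break
    if (attempt == 10L)
      abort("could not draw a sample containing both outcome classes in 10 attempts")
    inform(sprintf("single-class draw at seed %d; retrying", attempt_seed))
    attempt_seed <- derive_seed(seed, paste0("retry", attempt))
  }
  base_w <- 1 / spec$selection_probs[dat$stratum]
  w <- simulate_weights(
    n,
    mean = spec$weight_mean,
    sd = spec$weight_sd * sqrt(spec$weight_variance_scale),
    rank_driver = base_w,
    seed = derive_seed(attempt_seed, "weights")
  )
  out <- tibble::as_tibble(as.data.frame(dat$X))
  out$y <- as.integer(dat$y)
  out$weight <- w
  out$stratum <- as.integer(dat$stratum)
  attr(out, "spec_hash") <- spec_hash(spec)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "predictor_info") <- spec$predictors[c("name", "type", "n_levels")]
  class(out) <- c("survey_dataset", class(out))
  out
}

spec_hash <- function(spec) {
  rlang::hash(unclass(spec))
}

#' Write / read a survey dataset as CSV with a JSON sidecar
#'
#' The CSV holds one row per observation (columns `x1..xp`, `y`, `weight`,
#' `stratum`); the sidecar `<path>.json` records column types, category
#' counts, the generating spec hash, the seed and a timestamp, so a dataset
#' read back carries the same provenance as a freshly drawn one.
#'
#' @param data A `survey_dataset` (or compatible data frame).
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_survey_csv()` returns `path` invisibly;
#'   `read_survey_csv()` returns a `survey_dataset`.
#' @export
write_survey_csv <- function(data, path) {
  readr::write_csv(as.data.frame(data), path)
  info <- attr(data, "predictor_info")
  sidecar <- list(
    columns = names(data),
    predictor_types = if (!is.null(info)) as.list(stats::setNames(info$type, info$name)),
    category_counts = if (!is.null(info)) {
      stats::setNames(lapply(info$n_levels,
                             function(x) if (is.na(x)) NULL else x),
                      info$name)
    },
    spec_hash = attr(data, "spec_hash"),
    seed = attr(data, "seed"),
    generated_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$y <- as.integer(out$y)
  out$stratum <- as.integer(out$stratum)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path)
    attr(out, "spec_hash") <- sc$spec_hash
    attr(out, "seed") <- sc$seed
    if (!is.null(sc$predictor_types)) {
      attr(out, "predictor_info") <- tibble::tibble(
        name = names(sc$predictor_types),
        type = unlist(sc$predictor_types, use.names = FALSE),
        n_levels = unname(vapply(sc$category_counts,
                                 function(x) if (is.null(x)) NA_integer_ else as.integer(x),
                                 integer(1)))
      )
    }
  }
  class(out) <- c("survey_dataset", class(out))
  out
}
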