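#' The randomized-search hyperparameter space
#'
#' Eleven gradient-boosting hyperparameters with their sampling ranges:
#' learning parameters (number of trees, tree depth, learning rate) and
#' regularization parameters (row and column subsampling at tree and level
#' granularity, minimum child weight, minimum split loss, L1/L2 penalties,
#' early-stopping patience). Candidates are drawn independently uniform over
#' each range; the learning rate and the L1/L2 penalties are drawn
#' log-uniform because a raw-scale uniform over-samples large values (the
#' penalties, whose range starts at 0, are drawn log-uniform on
#' \[0.01, 10\]).
#'
#' @return A tibble with columns `param`, `lower`, `upper`, `type`
#'   (`"int"`/`"real"`), `scale` (`"uniform"`/`"log"`).
#' @export
#' @examples
#' hp_space()
hp_space <- function() {
  tibble::tribble(
    ~param,                  ~lower, ~upper, ~type,  ~scale,
    "n_trees",                  50,   2000, "int",  "uniform",
    "max_depth",                 2,     12, "int",  "uniform",
    "learning_rate",          0.01,    0.5, "real", "log",
    "row_subsample",           0.3,    1.0, "real", "uniform",
    "col_subsample_tree",      0.3,    1.0, "real", "uniform",
    "col_subsample_level",     0.3,    1.0, "real", "uniform",
    "min_child_weight",        0.5,     20, "real", "uniform",
    "min_split_loss",            0,     10, "real", "uniform",
    "l1_penalty",                0,     10, "real", "log",
    "l2_penalty",                0,     10, "real", "log",
    "early_stopping_rounds",     5,     50, "int",  "uniform"
  )
}

#' Sample hyperparameter candidates
#'
#' @param space A space tibble as returned by [hp_space()].
#' @param n Number of candidates (no de-duplication).
#' @param seed Integer seed.
#' @return A tibble with `n` rows and one column per parameter.
#' @export
#' @examples
#' sample_candidates(hp_space(), 5, seed = 1)
sample_candidates <- function(space = hp_space(), n, seed) {
  stopifnot(n >= 1, all(space$lower < space$upper))
  withr::with_seed(seed, {
    cols <- lapply(seq_len(nrow(space)), function(i) {
      row <- space[i, ]
      lo <- row$lower
      if (row$scale == "log") {
        lo <- max(lo, row$upper * 1e-3)
        x <- exp(stats::runif(n, log(lo), log(row$upper)))
      } else {
        x <- stats::runif(n, lo, row$upper)
      }
      if (row$type == "int") x <- as.integer(round(x))
      x
    })
    names(cols) <- space$param
    tibble::as_tibble(cols)
  })
}

#' Frozen default hyperparameters
#'
#' The boosting library's documented defaults, frozen as package constants
#' so the default-configuration sensitivity analysis does not drift with
#' library versions: 100 trees, depth 6, learning rate 0.3, no subsampling,
#' min_child_weight 1, no split-loss or L1 penalty, L2 penalty 1, and the
#' most permissive early-stopping patience in the space (50 rounds; the
#' library default disables stopping).
#'
#' @return A one-row tibble with the 11 hyperparameters.
#' @export
default_hyperparameters <- function() {
  tibble::tibble(
    n_trees = 100L, max_depth = 6L, learning_rate = 0.3,
    row_subsample = 1.0, col_subsample_tree = 1.0, col_subsample_level = 1.0,
    min_child_weight = 1, min_split_loss = 0, l1_penalty = 0, l2_penalty = 1,
    early_stopping_rounds = 50L
  )
}

#' Outcome-stratified k-fold assignment
#'
#' Assigns every row to one of `k` folds such that fold sizes differ by at
#' most one and each fold's class mix is within one observation of
#' proportional. Deterministic per seed.
#'
#' @param data A data frame with a 0/1 `y` column, or a 0/1 vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return An integer vector of fold ids in 1..k.
#' @export
#' @examples
#' table(make_folds(c(rep(1, 4), rep(0, 6)), k = 2, seed = 1))
make_folds <- function(data, k = 5, seed = 1) {
  y <- if (is.data.frame(data)) data$y else data
  n <- length(y)
  stopifnot(k >= 2, n >= k, length(unique(y)) == 2L)
  withr::with_seed(seed, {
    ord <- c(sample(which(y == 1)), sample(which(y == 0)))
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    folds
  })
}

# map a candidate row to xgb.params(); training weights must already be on
# the data
xgb_params_from <- function(hp) {
  xgboost::xgb.params(
    objective = "binary:logistic",
    eval_metric = "logloss",
    nthread = 1,
    tree_method = "hist",
    max_bin = 64,
    max_depth = as.integer(hp$max_depth),
    learning_rate = hp$learning_rate,
    subsample = hp$row_subsample,
    colsample_bytree = hp$col_subsample_tree,
    colsample_bylevel = hp$col_subsample_level,
    min_child_weight = hp$min_child_weight,
    gamma = hp$min_split_loss,
    alpha = hp$l1_penalty,
    lambda = hp$l2_penalty,
    seed = 0
  )
}

#' Out-of-fold predicted probabilities for one hyperparameter candidate
#'
#' For each fold, trains a gradient-boosted tree classifier on the
#' complement — passing per-row training weights normalized to mean 1 when
#' `use_weights` is `TRUE`, unit weights otherwise — and predicts
#' probabilities on the held-out fold, so no observation is predicted by a
#' model that saw it. Early stopping monitors log-loss on a seeded 10%
#' split of the training rows (out-of-fold rows are never touched). The
#' returned predictions always carry the original sampling weights,
#' whatever the training mode.
#'
#' @param data A `survey_dataset` (predictor columns `x*`, `y`, `weight`).
#' @param hp A one-row hyperparameter tibble (a row of
#'   [sample_candidates()] output or [default_hyperparameters()]).
#' @param folds Integer fold ids from [make_folds()].
#' @param use_weights Train with sampling weights?
#' @param seed Seed for the early-stopping validation splits.
#' @return A `prediction_set` tibble: `row_id`, `y_obs`, `p_hat`, `w`,
#'   `fold_id`.
#' @export
fit_oof <- function(data, hp, folds, use_weights, seed = 0) {
  X <- as_predictor_matrix(data)
  y <- data$y
  w <- data$weight
  n <- nrow(X)
  stopifnot(length(folds) == n)
  train_w <- if (use_weights) w / mean(w) else rep(1, n)
  p_hat <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    tr <- which(folds != f)
    te <- which(folds == f)
    n_val <- max(1L, round(0.1 * length(tr)))
    val <- withr::with_seed(derive_seed(seed, paste0("val-fold", f)),
                            sample(tr, n_val))
    fit <- tr[!tr %in% val]
    dtrain <- xgboost::xgb.DMatrix(X[fit, , drop = FALSE], label = y[fit],
                                   weight = train_w[fit], nthread = 1)
    dval <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = y[val],
                                 weight = train_w[val], nthread = 1)
    bst <- tryCatch(
      xgboost::xgb.train(
        params = xgb_params_from(hp),
        data = dtrain,
        nrounds = as.integer(hp$n_trees),
        evals = list(val = dval),
        early_stopping_rounds = as.integer(hp$early_stopping_rounds),
        verbose = 0
      ),
      error = function(e) abort(sprintf("training failed on fold %d: %s",
                                        f, conditionMessage(e)))
    )
    best_iter <- attributes(bst)$early_stop$best_iteration %||%
      xgboost::xgb.get.num.boosted.rounds(bst)
    p_hat[te] <- stats::predict(bst, X[te, , drop = FALSE],
                                iterationrange = c(1, best_iter))
  }
  out <- tibble::tibble(row_id = seq_len(n), y_obs = as.integer(y),
                        p_hat = p_hat, w = w, fold_id = as.integer(folds))
  class(out) <- c("prediction_set", class(out))
  out
}

#' Configure a gradient-boosting model by randomized search
#'
#' Evaluates `n_candidates` hyperparameter assignments by out-of-fold F1
#' under stratified `n_folds`-fold cross-validation and returns the best.
#' The configuration is weight-aware end to end: when `use_weights` is
#' `TRUE`, sampling weights enter both the training loss and the selection
#' metric (survey-weighted F1); when `FALSE` the whole pipeline ignores
#' them. Ties are broken by earliest candidate index. Folds and candidates
#' depend only on `(data, seed)`, so a weighted and an unweighted
#' configuration built with the same seed share folds and candidates.
#'
#' @param data A `survey_dataset`.
#' @param use_weights Build the weight-aware configuration?
#' @param space Hyperparameter space tibble.
#' @param n_candidates Number of randomized-search candidates.
#' @param n_folds Number of cross-validation folds.
#' @param threshold Classification cutoff used in the selection metric.
#' @param seed Integer seed driving folds, candidates and validation splits.
#' @return A `fitted_configuration`: list with `best_hp` (one-row tibble),
#'   `cv_score`, `oof` (a `prediction_set`), `weighted_training`,
#'   `candidates` (per-candidate scores), `folds`, `data_hash`, `threshold`,
#'   `seed`. `tidy()` returns the candidate table; `glance()` a one-row
#'   summary.
#' @export
#' @examples
#' \donttest{
#' spec <- baseline_population(1)
#' d <- draw_survey_sample(spec, 500, seed = 2)
#' cfg <- configure_model(d, use_weights = TRUE, n_candidates = 3, seed = 3)
#' glance(cfg)
#' }
configure_model <- function(data, use_weights, space = hp_space(),
                            n_candidates = 60, n_folds = 5,
                            threshold = 0.5, seed = 1) {
  stopifnot(n_candidates >= 1, n_folds >= 2)
  folds <- make_folds(data, n_folds, seed = derive_seed(seed, "folds"))
  cands <- sample_candidates(space, n_candidates,
                             seed = derive_seed(seed, "candidates"))
  scores <- rep(NA_real_, n_candidates)
  failures <- character(n_candidates)
  best <- NULL
  for (i in seq_len(n_candidates)) {
    preds <- tryCatch(
      fit_oof(data, cands[i, ], folds, use_weights,
              seed = derive_seed(seed, paste0("fit", i))),
      error = function(e) conditionMessage(e)
    )
    if (is.character(preds)) {
      failures[i] <- preds
      next
    }
    conf <- weighted_confusion(preds$y_obs, classify(preds$p_hat, threshold),
                               if (use_weights) preds$w else rep(1, nrow(preds)))
    scores[i] <- f1_score(conf)
    if (is.null(best) || scores[i] > best$cv_score) {
      best <- list(index = i, cv_score = scores[i], oof = preds)
    }
  }
  if (is.null(best))
    abort(paste0("all candidates failed; first error: ",
                 failures[failures != ""][1]))
  structure(list(
    best_hp = cands[best$index, ],
    best_index = best$index,
    cv_score = best$cv_score,
    oof = best$oof,
    weighted_training = use_weights,
    candidates = dplyr::mutate(cands, score = scores,
                               failure = dplyr::na_if(failures, "")),
    folds = folds,
    data_hash = dataset_hash(data),
    threshold = threshold,
    seed = as.integer(seed)
  ), class = "fitted_configuration")
}

#' @export
print.fitted_configuration <- function(x, ...) {
  cat(sprintf("<fitted_configuration> %s training, %d candidates, best OOF %s F1 = %.4f\n",
              if (x$weighted_training) "weighted" else "unweighted",
              nrow(x$candidates),
              if (x$weighted_training) "weighted" else "unweighted",
              x$cv_score))
  print(x$best_hp)
  invisible(x)
}

#' @rdname configure_model
#' @param x A `fitted_configuration`.
#' @param ... Unused.
#' @export
tidy.fitted_configuration <- function(x, ...) {
  dplyr::mutate(x$candidates,
                candidate = dplyr::row_number(),
                best = candidate == x$best_index,
                .before = 1)
}

#' @rdname configure_model
#' @export
glance.fitted_configuration <- function(x, ...) {
  tibble::tibble(
    weighted_training = x$weighted_training,
    n_candidates = nrow(x$candidates),
    n_failed = sum(!is.na(x$candidates$failure)),
    cv_score = x$cv_score,
    n_folds = length(unique(x$folds)),
    n_rows = nrow(x$oof),
    seed = x$seed
  )
}
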