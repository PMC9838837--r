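# small dataset fixtures built in code
small_data <- function(n = 300, seed = 9, axis = NULL, value = NULL) {
  spec <- baseline_population(1)
  if (!is.null(axis)) spec <- modify_population(spec, axis, value)
  draw_survey_sample(spec, n, seed = seed)
}

test_that("folds are balanced, outcome-stratified and deterministic", {
  y10 <- rep(c(0L, 1L), 5)
  f <- make_folds(y10, k = 5, seed = 1)
  expect_equal(unname(sort(table(f))), rep(2L, 5), ignore_attr = TRUE)

  y11 <- c(rep(0L, 6), rep(1L, 5))
  f11 <- make_folds(y11, k = 5, seed = 1)
  expect_equal(sort(as.integer(table(f11)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L))

  y <- c(rep(1L, 4), rep(0L, 16))
  f2 <- make_folds(y, k = 2, seed = 3)
  expect_equal(as.integer(table(f2[y == 1])), c(2L, 2L))

  expect_identical(make_folds(y, 2, seed = 3), make_folds(y, 2, seed = 3))
  expect_error(make_folds(c(0L, 1L), k = 5, seed = 1))

  # stratification holds on a realistic dataset too
  d <- small_data(500)
  fd <- make_folds(d, k = 5, seed = 2)
  pos_per_fold <- table(fd[d$y == 1])
  expect_lte(diff(range(pos_per_fold)), 1)
  expect_lte(diff(range(table(fd))), 1)
})

test_that("candidate sampling respects ranges, scales and seeds", {
  space <- hp_space()
  expect_equal(nrow(space), 11L)
  cands <- sample_candidates(space, 200, seed = 5)
  expect_equal(nrow(cands), 200L)
  for (i in seq_len(nrow(space))) {
    p <- space$param[i]
    expect_true(all(cands[[p]] >= space$lower[i] & cands[[p]] <= space$upper[i]),
                info = p)
  }
  expect_true(all(cands$n_trees == round(cands$n_trees)))
  expect_identical(cands, sample_candidates(space, 200, seed = 5))
  expect_false(identical(cands, sample_candidates(space, 200, seed = 6)))

  # log-uniform learning rate: empirical median near sqrt(0.01 * 0.5)
  big <- sample_candidates(space, 10000, seed = 7)
  expect_gt(median(big$learning_rate), 0.05)
  expect_lt(median(big$learning_rate), 0.1)
})

test_that("default hyperparameters are frozen and inside the space", {
  d1 <- default_hyperparameters()
  expect_identical(d1, default_hyperparameters())
  space <- hp_space()
  expect_equal(ncol(d1), 11L)
  for (i in seq_len(nrow(space))) {
    p <- space$param[i]
    expect_true(d1[[p]] >= space$lower[i] && d1[[p]] <= space$upper[i],
                info = p)
  }
})

test_that("out-of-fold predictions partition the data and ignore uniform weights", {
  d <- small_data(300)
  folds <- make_folds(d, 5, seed = 1)
  hp <- default_hyperparameters()

  oof <- fit_oof(d, hp, folds, use_weights = TRUE, seed = 2)
  expect_equal(sort(oof$row_id), 1:300)
  expect_true(all(oof$p_hat >= 0 & oof$p_hat <= 1))
  expect_equal(oof$w, d$weight)
  expect_equal(oof$fold_id, folds)

  # uniform weights: weighted and unweighted training coincide
  du <- d
  du$weight <- rep(3.7, nrow(du))
  p_w <- fit_oof(du, hp, folds, use_weights = TRUE, seed = 2)$p_hat
  p_u <- fit_oof(du, hp, folds, use_weights = FALSE, seed = 2)$p_hat
  expect_equal(p_w, p_u, tolerance = 1e-9)

  # weight-scale invariance of training
  d10 <- d
  d10$weight <- d$weight * 10
  p_1 <- fit_oof(d, hp, folds, use_weights = TRUE, seed = 2)$p_hat
  p_10 <- fit_oof(d10, hp, folds, use_weights = TRUE, seed = 2)$p_hat
  expect_equal(p_1, p_10, tolerance = 1e-9)
})

test_that("stronger predictors yield better out-of-fold discrimination than the null", {
  folds_for <- function(d) make_folds(d, 5, seed = 4)
  hp <- default_hyperparameters()
  oof_f1 <- function(d) {
    oof <- fit_oof(d, hp, folds_for(d), use_weights = FALSE, seed = 5)
    f1_score(weighted_confusion(oof$y_obs, classify(oof$p_hat)))
  }
  strong <- oof_f1(small_data(600, seed = 21, axis = "beta_scale", value = 2))
  null_ <- oof_f1(small_data(600, seed = 21, axis = "null"))
  expect_gt(strong, null_)
})

test_that("configure_model honours the argmax contract and reproduces itself", {
  d <- small_data(300)
  cfg1 <- configure_model(d, use_weights = TRUE, n_candidates = 1, seed = 3)
  expect_equal(cfg1$best_index, 1L)
  expect_equal(nrow(cfg1$candidates), 1L)

  cfg <- configure_model(d, use_weights = TRUE, n_candidates = 4, seed = 3)
  expect_true(all(cfg$cv_score >= cfg$candidates$score, na.rm = TRUE))
  expect_equal(cfg$cv_score, max(cfg$candidates$score, na.rm = TRUE))
  expect_s3_class(cfg$oof, "prediction_set")
  expect_equal(sort(cfg$oof$row_id), seq_len(nrow(d)))

  cfg2 <- configure_model(d, use_weights = TRUE, n_candidates = 4, seed = 3)
  expect_identical(cfg$best_hp, cfg2$best_hp)
  expect_identical(cfg$oof$p_hat, cfg2$oof$p_hat)

  g <- glance(cfg)
  expect_equal(g$n_candidates, 4L)
  expect_equal(g$cv_score, cfg$cv_score)
  td <- tidy(cfg)
  expect_equal(sum(td$best), 1L)
})
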