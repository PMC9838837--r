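test_that("simulate_weights handles the degenerate and coupled cases", {
  expect_equal(simulate_weights(10, mean = 9565, sd = 0,
                                rank_driver = 1:10, seed = 1),
               rep(9565, 10))
  expect_error(simulate_weights(10, mean = 9565, sd = -1,
                                rank_driver = 1:10, seed = 1), "nonnegative")

  # comonotone coupling: weight order matches the rank driver's order
  driver <- c(5, 1, 3, 2, 4)
  w <- simulate_weights(5, 100, 50, rank_driver = driver, seed = 7)
  expect_equal(order(w), order(driver))

  # ties broken by row index: tied drivers get increasing weights by row
  w2 <- simulate_weights(4, 100, 50, rank_driver = c(1, 1, 1, 1), seed = 7)
  expect_equal(w2, sort(w2))

  expect_identical(simulate_weights(100, 100, 50, rep(1, 100), seed = 3),
                   simulate_weights(100, 100, 50, rep(1, 100), seed = 3))
})

test_that("survey samples have valid structure and are bitwise reproducible", {
  spec <- baseline_population(1)
  d <- draw_survey_sample(spec, 1000, seed = 5)
  expect_s3_class(d, "survey_dataset")
  expect_equal(nrow(d), 1000L)
  expect_setequal(unique(d$y), c(0L, 1L))
  expect_true(all(d$weight > 0))
  expect_true(all(d$stratum %in% seq_len(spec$n_strata)))
  expect_equal(ncol(d), 27L + 3L)

  expect_identical(draw_survey_sample(spec, 1000, seed = 5), d)
  expect_false(identical(draw_survey_sample(spec, 1000, seed = 6), d))
})

test_that("baseline prevalence is plausible and weights are informative", {
  spec <- baseline_population(1)
  d <- draw_survey_sample(spec, 10000, seed = 11)
  prev <- mean(d$y)
  expect_gt(prev, 0.25)
  expect_lt(prev, 0.50)

  # unequal selection: weighted prevalence must differ beyond Monte-Carlo
  # noise (the precondition for any scenario divergence)
  wprev <- weighted.mean(d$y, d$weight)
  se <- sd(d$y) / sqrt(nrow(d))
  expect_gt(abs(wprev - prev), 3 * se)
})

test_that("the simple-random-sample limit yields constant weights", {
  spec <- baseline_population(1, selection_probs = rep(0.5, 4),
                              weight_sd = 0)
  d <- draw_survey_sample(spec, 500, seed = 2)
  expect_true(all(d$weight == spec$weight_mean))
})

test_that("under the null, outcome is independent of predictors and weights", {
  spec0 <- modify_population(baseline_population(1), "null")
  d <- draw_survey_sample(spec0, 100000, seed = 3)

  # weighted and unweighted prevalence agree up to sampling noise
  prev <- mean(d$y)
  wprev <- weighted.mean(d$y, d$weight)
  se <- sd(d$y) / sqrt(nrow(d))
  expect_lt(abs(wprev - prev), 3 * se)

  # predictor-outcome correlations at chance level (family-wise bound for
  # 27 simultaneous checks)
  cors <- vapply(grep("^x", names(d), value = TRUE),
                 function(cl) cor(d[[cl]], d$y), numeric(1))
  z <- abs(cors) * sqrt(nrow(d))
  expect_true(all(z < 3.8))
})

test_that("datasets round-trip through CSV with sidecar provenance", {
  spec <- baseline_population(1)
  d <- draw_survey_sample(spec, 200, seed = 4)
  path <- file.path(withr::local_tempdir(), "data.csv")
  write_survey_csv(d, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))

  d2 <- read_survey_csv(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
  expect_identical(attr(d2, "spec_hash"), attr(d, "spec_hash"))
  expect_identical(attr(d2, "seed"), attr(d, "seed"))
  info <- attr(d2, "predictor_info")
  expect_equal(info$type, attr(d, "predictor_info")$type)
})
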