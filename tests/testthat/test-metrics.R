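# independent oracle: expand each row to w_i unit-weight copies and count
expand_by_weight <- function(y, yp, w) {
  idx <- rep(seq_along(y), times = w)
  list(y = y[idx], yp = yp[idx])
}

test_that("classify uses an inclusive threshold", {
  expect_equal(classify(c(0.2, 0.5, 0.8), 0.5), c(0L, 1L, 1L))
  expect_equal(classify(c(0.49), 0.5), 0L)
  expect_equal(classify(runif(20), 1e-12), rep(1L, 20))
  expect_error(classify(0.5, 0))
})

test_that("weighted confusion cells match the hand-worked example and conserve weight", {
  conf <- weighted_confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), w = c(2, 1, 1, 3))
  expect_equal(conf$tp, 2)
  expect_equal(conf$fn, 1)
  expect_equal(conf$fp, 1)
  expect_equal(conf$tn, 3)
  expect_equal(conf$tp + conf$fp + conf$fn + conf$tn, 7)

  expect_equal(f1_score(conf), 2 / 3)
  expect_equal(sensitivity(conf), 2 / 3)
  expect_equal(ppv(conf), 2 / 3)

  expect_error(weighted_confusion(c(1, 0), c(1, 0, 1), c(1, 1, 1)), "length")
  expect_error(weighted_confusion(c(1, 0), c(1, 0), c(1, -1)), "positive")
})

test_that("degenerate confusion cells follow the defined-zero convention", {
  perfect <- weighted_confusion(c(1, 1, 0), c(1, 1, 0), c(2, 3, 1))
  expect_equal(f1_score(perfect), 1)

  no_tp <- weighted_confusion(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(f1_score(no_tp), 0)

  empty <- weighted_confusion(c(0, 0), c(0, 0), c(1, 1))
  expect_warning(val <- f1_score(empty), "defined as 0")
  expect_equal(val, 0)
})

test_that("weighted metrics equal unweighted metrics on weight-expanded data", {
  withr::with_seed(42, {
    for (case in 1:50) {
      n <- sample(5:50, 1)
      y <- rbinom(n, 1, runif(1, 0.2, 0.8))
      yp <- rbinom(n, 1, runif(1, 0.2, 0.8))
      w <- sample(1:10, n, replace = TRUE)
      conf_w <- weighted_confusion(y, yp, w)
      ex <- expand_by_weight(y, yp, w)
      conf_e <- weighted_confusion(ex$y, ex$yp)
      expect_identical(f1_score(conf_w), f1_score(conf_e))
      expect_identical(sensitivity(conf_w), sensitivity(conf_e))
      expect_identical(ppv(conf_w), ppv(conf_e))
    }
  })
})

test_that("metrics are invariant to weight scale and respect bounds", {
  withr::with_seed(7, {
    for (case in 1:20) {
      n <- 40
      y <- rbinom(n, 1, 0.4)
      yp <- rbinom(n, 1, 0.4)
      w <- rexp(n) + 0.05
      c1 <- weighted_confusion(y, yp, w)
      c2 <- weighted_confusion(y, yp, w * 17.3)
      expect_equal(f1_score(c1), f1_score(c2), tolerance = 1e-12)
      expect_equal(sensitivity(c1), sensitivity(c2), tolerance = 1e-12)
      expect_equal(ppv(c1), ppv(c2), tolerance = 1e-12)
      expect_true(f1_score(c1) >= 0 && f1_score(c1) <= 1)
      expect_equal(c1$tp + c1$fp + c1$fn + c1$tn, sum(w), tolerance = 1e-9)

      # harmonic-mean form agrees with the 2tp/(2tp+fp+fn) form
      if (c1$tp > 0) {
        s <- sensitivity(c1); p <- ppv(c1)
        expect_equal(f1_score(c1), 2 * s * p / (s + p), tolerance = 1e-12)
      }
    }
  })
})

test_that("bootstrap CI is degenerate for a perfect classifier and reproducible", {
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  preds <- tibble::tibble(y_obs = y, p_hat = ifelse(y == 1, 0.9, 0.1),
                          w = rexp(n) + 0.1)
  res <- bootstrap_metric(preds, weighted = TRUE, n_boot = 200, seed = 1)
  expect_equal(res$estimate, 1)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)

  res2 <- bootstrap_metric(preds, weighted = TRUE, n_boot = 200, seed = 1)
  expect_identical(tidy(res), tidy(res2))
  expect_error(bootstrap_metric(preds, n_boot = 50, seed = 1), "n_boot")
})

test_that("bootstrap CIs shrink with sample size", {
  width <- function(n, seed) {
    withr::with_seed(seed, {
      p <- runif(n)
      y <- rbinom(n, 1, p)
      preds <- tibble::tibble(y_obs = y, p_hat = p, w = rexp(n) + 0.1)
      r <- bootstrap_metric(preds, n_boot = 300, seed = seed)
      r$ci_high - r$ci_low
    })
  }
  w_small <- mean(vapply(1:10, function(s) width(500, s), numeric(1)))
  w_large <- mean(vapply(1:10, function(s) width(10000, s), numeric(1)))
  expect_lt(w_large, w_small)
})
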