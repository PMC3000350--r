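# Bootstrap confidence intervals and shuffle significance.

test_that("resampling is bit-reproducible under a fixed seed", {
  pair <- copy_pair(2^11, lag = 2, seed = 51)
  cfg <- bootstrap_config(n_resamples = 20, seed = 99)
  ci1 <- bootstrap_ci(pair$x, pair$y, delta = 2, omega = 1, measure = "imi",
                      config = cfg, bias_correct = FALSE)
  ci2 <- bootstrap_ci(pair$x, pair$y, delta = 2, omega = 1, measure = "imi",
                      config = cfg, bias_correct = FALSE)
  expect_identical(ci1, ci2)
  thr1 <- significance_threshold(pair$x, pair$y, delta = 2, omega = 1,
                                 measure = "imi",
                                 config = bootstrap_config(20, seed = 98,
                                                           mode = "significance"),
                                 bias_correct = FALSE)
  thr2 <- significance_threshold(pair$x, pair$y, delta = 2, omega = 1,
                                 measure = "imi",
                                 config = bootstrap_config(20, seed = 98,
                                                           mode = "significance"),
                                 bias_correct = FALSE)
  expect_identical(thr1, thr2)
})

test_that("a measure constant under resampling yields a zero-width interval", {
  x <- rep(0L, 400)
  y <- rep(c(0L, 1L), 200)
  ci <- bootstrap_ci(x, y, delta = 0, omega = 1, measure = "imi",
                     config = bootstrap_config(25, seed = 1), bias_correct = FALSE)
  expect_equal(unname(ci), c(0, 0))
})

test_that("the copy pair's interval tightly contains one bit", {
  pair <- copy_pair(2^13, lag = 3, seed = 52)
  ci <- bootstrap_ci(pair$x, pair$y, delta = 3, omega = 2, measure = "imi",
                     config = bootstrap_config(100, seed = 7), bias_correct = TRUE)
  expect_lte(ci[["low"]], 1); expect_gte(ci[["high"]], 1)
  expect_lt(ci[["high"]] - ci[["low"]], 0.05)
  thr <- significance_threshold(pair$x, pair$y, delta = 3, omega = 2,
                                measure = "imi",
                                config = bootstrap_config(50, seed = 8,
                                                          mode = "significance"),
                                bias_correct = FALSE)
  obs <- imi(pair$x, pair$y, deltas = 3, omega = 2, bias_correct = FALSE)$value
  expect_gt(obs, 10 * thr)
})

test_that("a constant Y gives a zero threshold and zero observed value", {
  withr::with_seed(53, x <- rbinom(500, 1, 0.4))
  y <- rep(0L, 500)
  thr <- significance_threshold(x, y, delta = 0, omega = 1, measure = "imi",
                                config = bootstrap_config(20, seed = 3,
                                                          mode = "significance"),
                                bias_correct = FALSE)
  expect_equal(thr, 0)
  expect_equal(imi(x, y, deltas = 0, omega = 1, bias_correct = FALSE)$value, 0)
})

test_that("null-pair intervals cover zero and flags stay rare", {
  withr::with_seed(54, {
    x <- rbinom(2^14, 1, 0.2); y <- rbinom(2^14, 1, 0.2)
  })
  ci <- bootstrap_ci(x, y, delta = 1, omega = 1, measure = "imi",
                     config = bootstrap_config(50, seed = 4), bias_correct = TRUE)
  expect_lte(ci[["low"]], 0.002)
  expect_gte(ci[["high"]], -0.002)
  # light null calibration (the full 50-replicate version runs elsewhere)
  flags <- 0L; total <- 0L
  for (r in 1:8) {
    withr::with_seed(100 + r, {
      xn <- rbinom(2^11, 1, 0.3); yn <- rbinom(2^11, 1, 0.3)
    })
    for (d in c(-2L, 0L, 2L)) {
      thr <- significance_threshold(xn, yn, delta = d, omega = 1, measure = "imi",
                                    config = bootstrap_config(60, seed = 200 + r,
                                                              mode = "significance"),
                                    bias_correct = FALSE)
      obs <- imi(xn, yn, deltas = d, omega = 1, bias_correct = FALSE)$value
      total <- total + 1L
      if (obs > thr) flags <- flags + 1L
    }
  }
  expect_lt(flags / total, 0.25)
})

test_that("profile-level inference columns honour the invariants", {
  pair <- copy_pair(2^12, lag = 2, seed = 55)
  prof <- imi(pair$x, pair$y, deltas = 0:4, omega = 1, bias_correct = FALSE,
              ci = TRUE, significance = TRUE, n_resamples = 30, seed = 9)
  expect_true(all(c("ci_low", "ci_high", "sig_threshold") %in% names(prof)))
  expect_true(all(prof$ci_low <= prof$ci_high))
  expect_true(prof$value[prof$delta == 2] > prof$sig_threshold[prof$delta == 2])
})
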