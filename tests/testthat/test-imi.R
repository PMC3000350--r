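# Incremental mutual information: analytic limits, oracle equivalence,
# estimator properties.

test_that("a deterministic lagged copy carries exactly one bit at its lag", {
  pair <- copy_pair(2^13, lag = 3, seed = 31)
  prof <- imi(pair$x, pair$y, deltas = -5:5, omega = 2, bias_correct = FALSE)
  expect_equal(prof$value[prof$delta == 3], 1, tolerance = 0.01)
  # the copy is fully predicted by the context once Y[n-3] enters the window
  expect_equal(prof$value[prof$delta == 1], 0, tolerance = 1e-12)

  nprof <- normalized_imi(pair$x, pair$y, deltas = 3, omega = 2, bias_correct = FALSE)
  expect_equal(nprof$value, 1, tolerance = 1e-12)
  # normalization denominator vanishes where the context determines X
  nprof1 <- normalized_imi(pair$x, pair$y, deltas = 1, omega = 2, bias_correct = FALSE)
  expect_equal(nprof1$value, 0)
})

test_that("independent trains give near-zero IMI at every delay", {
  withr::with_seed(32, {
    x <- rbinom(2^18, 1, 0.2); y <- rbinom(2^18, 1, 0.2)
  })
  prof <- imi(x, y, deltas = -10:10, omega = 2, bias_correct = FALSE)
  expect_true(all(abs(prof$value) < 0.005))
})

test_that("uncorrected IMI equals brute-force conditional mutual information", {
  # exhaustive-histogram oracle, exact to numerical precision
  cases <- list(
    copy_pair(2^10, lag = 2, seed = 33),
    withr::with_seed(34, list(x = rbinom(2^12, 1, 0.3), y = rbinom(2^12, 1, 0.3))),
    local({
      pair <- simulate_pair(circuit_spec("static", epsilon = 0.8, delay_star = 2,
                                         input_mode = "independent_white",
                                         n_samples = 2^12, seed = 35))
      list(x = as.integer(pair$x), y = as.integer(pair$y))
    }))
  for (pair in cases) {
    for (delta in c(-2L, 0L, 2L, 3L)) {
      cw <- build_conditioning_words(pair$x, pair$y, delta, omega = 1)
      oracle <- brute_cmi(cw$x_s, cw$y_s, cw$word)
      prof <- imi(pair$x, pair$y, deltas = delta, omega = 1, bias_correct = FALSE)
      expect_lt(abs(prof$value - oracle), 1e-12)
    }
  }
})

test_that("uncorrected IMI is nonnegative and H(X|V) shrinks with omega", {
  withr::with_seed(36, {
    pair <- simulate_pair(circuit_preset("dynamic", n_samples = 2^13, seed = 36))
    prof <- imi(pair$x, pair$y, deltas = -6:6, omega = 1, bias_correct = FALSE)
    expect_true(all(prof$value >= -1e-9))
    # restrict both window sizes to a common valid-sample set
    cw1 <- build_conditioning_words(pair$x, pair$y, 0, omega = 1)
    cw2 <- build_conditioning_words(pair$x, pair$y, 0, omega = 2)
    common <- intersect(cw1$n, cw2$n)
    h1 <- conditional_entropy(cw1$x_s[match(common, cw1$n)],
                              cw1$word[match(common, cw1$n)])$value
    h2 <- conditional_entropy(cw2$x_s[match(common, cw2$n)],
                              cw2$word[match(common, cw2$n)])$value
    expect_lte(h2, h1 + 1e-9)
  })
})

test_that("past-only conditioning fails only above the connection delay", {
  pair <- simulate_pair(circuit_preset("static_correlated", n_samples = 2^17, seed = 5))
  full <- normalized_imi(pair$x, pair$y, deltas = 0:8, omega = 2)
  past <- past_only_imi(pair$x, pair$y, deltas = 0:8, omega = 2, normalized = TRUE)
  below <- full$delta < 4 & full$delta >= 0
  above <- full$delta > 4
  # below the connection delay both conditionings remove the slow input
  expect_lt(max(abs(past$value[below] - full$value[below])), 0.005)
  # above it, the past-only variant leaks the input correlations
  expect_gt(sum(past$value[above]), 3 * sum(full$value[above]))
})

test_that("insufficient samples for the quarter splits is a clear error", {
  pair <- copy_pair(16, lag = 1, seed = 37)
  expect_error(imi(pair$x, pair$y, deltas = 5, omega = 2, bias_correct = TRUE),
               "quadratic extrapolation needs")
})
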