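# Dichotomized-Gaussian circuit simulator.

test_that("the Gaussian kernel has unit peak and exact half-maximum crossings", {
  g <- gaussian_filter(4, 3)
  expect_equal(which.max(g) - 1L, 4L)
  expect_equal(max(g), 1)
  # half width read as HWHM: value 0.5 one half-width from the peak
  expect_equal(g[4 + 3 + 1], 0.5, tolerance = 1e-12)
  expect_equal(g[4 - 3 + 1], 0.5, tolerance = 1e-12)
  # a vanishing half width approaches a unit impulse
  gi <- gaussian_filter(0, 0.1)
  expect_equal(gi[1], 1)
  expect_lt(sum(gi[-1]), 1e-10)
})

test_that("marginal spike probabilities follow the Gaussian tail", {
  spec <- circuit_spec("none", input_mode = "independent_white",
                       theta = 1, n_samples = 2^18, seed = 61)
  pair <- simulate_pair(spec)
  p <- 1 - pnorm(1)
  se <- sqrt(p * (1 - p) / 2^18)
  expect_lt(abs(mean(pair$x) - p), 3 * se)
  expect_lt(abs(mean(pair$y) - p), 3 * se)
  # filtered inputs are rescaled to unit variance: same marginal rate
  spec2 <- circuit_spec("none", input_mode = "correlated_input_on_Y",
                        n_samples = 2^18, seed = 62)
  expect_lt(abs(mean(simulate_pair(spec2)$y) - p), 0.01)
})

test_that("simulation is seed-reproducible and epsilon = 0 removes the connection", {
  spec <- circuit_preset("static_correlated", n_samples = 2^12, seed = 63)
  p1 <- simulate_pair(spec); p2 <- simulate_pair(spec)
  expect_identical(as.integer(p1$x), as.integer(p2$x))
  expect_identical(as.integer(p1$y), as.integer(p2$y))

  none <- circuit_spec("none", input_mode = "independent_white",
                       n_samples = 2^12, seed = 64)
  eps0_static <- circuit_spec("static", epsilon = 0, delay_star = 4,
                              input_mode = "independent_white",
                              n_samples = 2^12, seed = 64)
  eps0_dynamic <- circuit_spec("dynamic", epsilon = 0,
                               input_mode = "independent_white",
                               n_samples = 2^12, seed = 64)
  base <- simulate_pair(none)
  for (s in list(eps0_static, eps0_dynamic)) {
    alt <- simulate_pair(s)
    expect_identical(as.integer(alt$x), as.integer(base$x))
    expect_identical(as.integer(alt$y), as.integer(base$y))
  }
})

test_that("shared white sources show the predicted lag-zero dependency", {
  rho <- 0.5; theta <- 1
  spec <- circuit_spec("none", input_mode = "shared_white", shared_corr = rho,
                       n_samples = 2^18, seed = 65)
  pair <- simulate_pair(spec)
  # orthant probability of the bivariate normal: P(Z1 >= t, Z2 >= t)
  p11 <- stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((theta - rho * z) / sqrt(1 - rho^2),
                                   lower.tail = FALSE)
  }, theta, Inf)$value
  p <- 1 - pnorm(theta)
  r_expected <- (p11 - p^2) / (p * (1 - p))
  cc <- cross_correlation(pair$x, pair$y, deltas = 0)
  expect_equal(cc$value, r_expected, tolerance = 0.05)
})

test_that("trial simulation freezes the stimulus and honours the weight limits", {
  base <- list(connection = "none", input_mode = "independent_white",
               n_trials = 6, trial_length = 400, frozen_stimulus = TRUE)
  all_stim <- do.call(circuit_spec, c(base, stimulus_weight = 1, seed = 66))
  tr <- simulate_trials(all_stim)
  expect_true(all(tr$y == rep(tr$y[1, ], each = 6)))

  no_stim <- do.call(circuit_spec, c(base, stimulus_weight = 0, seed = 67))
  tr0 <- simulate_trials(no_stim)
  expect_lt(abs(cor(tr0$y[1, ], tr0$y[2, ])), 0.15)

  expect_error(simulate_trials(circuit_spec("none", n_trials = 1,
                                            trial_length = 100,
                                            frozen_stimulus = TRUE)),
               "n_trials")
  expect_error(simulate_trials(circuit_spec("none", n_trials = 4,
                                            trial_length = 100)),
               "frozen_stimulus")
})

test_that("invalid specifications are rejected", {
  expect_error(circuit_spec("static", delay_star = 2.5), "integer")
  expect_error(circuit_spec("none", input_mode = "independent_white",
                            shared_corr = 0.3), "shared input mode")
})
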