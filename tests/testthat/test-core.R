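# Binning and conditioning-vector construction.

test_that("bin_spike_times places spikes in half-open bins", {
  bt <- bin_spike_times(c(0.001, 0.005), 0.002, t_start = 0, t_end = 0.008)
  expect_equal(as.integer(bt), c(1L, 0L, 1L, 0L))
  expect_equal(attr(bt, "bin_width"), 0.002)

  empty <- bin_spike_times(numeric(0), 0.002, t_start = 0, t_end = 0.004)
  expect_equal(as.integer(empty), c(0L, 0L))

  # unsorted input is fine
  bt2 <- bin_spike_times(c(0.005, 0.001), 0.002, t_start = 0, t_end = 0.008)
  expect_equal(as.integer(bt2), as.integer(bt))
})

test_that("two spikes in one bin is an error naming the bin", {
  expect_error(bin_spike_times(c(0.0010, 0.0015), 0.002, t_start = 0, t_end = 0.004),
               "bin 0.*smaller.*bin_width")
  expect_error(bin_spike_times(c(0.001), 0.002, t_start = 0.01, t_end = 0.005),
               "t_end")
})

test_that("bin centers of nonzero bins recover each spike's bin", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      spikes <- sort(runif(40, 0, 1))
      spikes <- spikes[c(TRUE, diff(spikes) > 0.006)]  # enforce one per bin
      bt <- bin_spike_times(spikes, 0.005, t_start = 0, t_end = 1)
      centers <- spike_bin_centers(bt)
      expect_equal(floor(centers / 0.005), floor(spikes / 0.005))
    }
  })
})

test_that("conditioning words follow the fixed bit layout", {
  # all-zero trains: every word 0, all aligned samples 0
  cw0 <- build_conditioning_words(rep(0L, 30), rep(0L, 30), delta = 2, omega = 2)
  expect_true(all(cw0$word == 0L))
  expect_true(all(cw0$x_s == 0L) && all(cw0$y_s == 0L))

  # N = 9, delta = 0, omega = 1: valid n are the 7 interior samples and the
  # word is (X[n-1], X[n+1], Y[n-1], Y[n+1]) packed most-significant first
  x <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L)
  y <- c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L)
  cw <- build_conditioning_words(x, y, delta = 0, omega = 1)
  expect_length(cw$word, 7L)
  expect_equal(cw$n, 2:8)
  n <- 5L  # 1-based
  expected_word <- x[n - 1] * 8L + x[n + 1] * 4L + y[n - 1] * 2L + y[n + 1]
  expect_equal(cw$word[cw$n == n], expected_word)
  expect_equal(cw$x_s, x[2:8])

  # alternating pair, delta = 1, omega = 1: word bits at 0-based n = 2 are
  # (X[1], X[3], Y[0], Y[2]) = (1,1,1,1)
  xa <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L)
  ya <- c(1L, 0L, 1L, 0L, 1L, 0L, 1L)
  cwa <- build_conditioning_words(xa, ya, delta = 1, omega = 1)
  expect_equal(cwa$word[cwa$n == 3L], 15L)
})

test_that("valid-sample counts and mirror symmetry hold across delays", {
  withr::with_seed(7, {
    x <- rbinom(64, 1, 0.3); y <- rbinom(64, 1, 0.3)
    for (omega in 1:3) for (delta in -4:4) {
      cw <- build_conditioning_words(x, y, delta, omega)
      expect_equal(length(cw$word), 64L - 2L * omega - abs(delta))
      mirror <- build_conditioning_words(y, x, -delta, omega)
      expect_equal(length(mirror$word), length(cw$word))
      expect_true(all(cw$word >= 0 & cw$word < 2^(4 * omega)))
    }
  })
})

test_that("past-only words carry half the bits", {
  withr::with_seed(8, {
    x <- rbinom(40, 1, 0.5); y <- rbinom(40, 1, 0.5)
    cw <- build_conditioning_words(x, y, delta = 2, omega = 2, past_only = TRUE)
    expect_equal(cw$bits, 4L)
    expect_true(all(cw$word < 16L))
  })
})

test_that("degenerate inputs are rejected", {
  expect_error(build_conditioning_words(rep(0L, 4), rep(0L, 4), delta = 0, omega = 2),
               "too short")
  expect_error(build_conditioning_words(rep(0L, 10), rep(0L, 9), delta = 0, omega = 1),
               "same length")
  expect_error(build_conditioning_words(c(0L, 2L, 0L, 1L, 0L, 1L, 0L),
                                        rep(0L, 7), delta = 0, omega = 1),
               "0/1")
})
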