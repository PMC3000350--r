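# Dichotomized-Gaussian two-neuron circuit simulator. Each neuron spikes
# when its underlying Gaussian signal (noise input plus, for X, the scaled
# drive from Y) crosses a threshold; binary trains with controlled marginal
# rates and temporal/shared correlations follow.

#' Discrete causal Gaussian filter kernel
#'
#' `g[k] = exp(-(k - peak_delay)^2 / (2 sigma^2))` on integer lags `k >= 0`,
#' with `sigma = half_width / sqrt(2 ln 2)` (the half width is read as the
#' half-width at half-maximum), truncated beyond four sigma from the peak,
#' and normalized to unit peak so that a connection strength multiplying the
#' filtered train keeps its meaning.
#'
#' @param peak_delay lag of the kernel maximum, in bins (>= 0).
#' @param half_width half-width at half-maximum, in bins (> 0).
#' @return Numeric vector `g`; `g[k + 1]` is the weight at lag `k`.
#' @export
gaussian_filter <- function(peak_delay, half_width) {
  stopifnot(is_wholenumber(peak_delay), peak_delay >= 0,
            is.numeric(half_width), length(half_width) == 1L, half_width > 0)
  sigma <- half_width / sqrt(2 * log(2))
  kmax <- ceiling(peak_delay + 4 * sigma)
  k <- 0:kmax
  g <- exp(-(k - peak_delay)^2 / (2 * sigma^2))
  g[abs(k - peak_delay) > 4 * sigma] <- 0
  g
}

input_modes <- c("independent_white", "correlated_input_on_Y",
                 "shared_correlated", "shared_white")

#' Specify a simulated two-neuron circuit
#'
#' Parameters of the dichotomized-Gaussian pair: `Y[n] = 1{s_y[n] >= theta}`
#' with `s_y` a unit-variance Gaussian input (white, or temporally
#' correlated by filtering with a zero-peak-delay Gaussian kernel), and
#' `X[n] = 1{s_x[n] + epsilon * drive[n] >= theta}` where the drive is the
#' Gaussian-filtered activity of Y (dynamic connection), `Y[n - delay_star]`
#' (static connection) or absent. In the shared-input modes the two raw
#' noise sources have correlation `shared_corr`, imposed before any
#' filtering; filtered inputs are rescaled to unit variance so the threshold
#' keeps the same marginal spike probability `1 - pnorm(theta)` across
#' modes.
#'
#' @param connection `"none"`, `"static"` or `"dynamic"`.
#' @param epsilon connection strength (>= 0, dimensionless).
#' @param theta spiking threshold in SD units of the input (default 1).
#' @param delay_star static-connection delay in bins.
#' @param filter_peak_delay,filter_half_width Gaussian kernel of the dynamic
#'   connection (bins); the input-correlation kernel reuses
#'   `filter_half_width` with a peak delay of zero.
#' @param input_mode `"independent_white"` (both inputs white, uncorrelated),
#'   `"correlated_input_on_Y"` (Y's input temporally correlated, X's white),
#'   `"shared_correlated"` (both inputs temporally correlated, sources
#'   correlated `shared_corr`), or `"shared_white"` (both white, correlated
#'   `shared_corr`).
#' @param shared_corr correlation coefficient of the two raw noise sources
#'   (0..1; only used by the shared modes).
#' @param n_samples number of time bins.
#' @param seed integer seed; all outputs are bit-reproducible from it.
#' @param n_trials,trial_length,frozen_stimulus,stimulus_weight,stimulus_half_width
#'   trial mode (see [simulate_trials()]): number of trials, bins per trial,
#'   whether one slow shared stimulus realization is frozen across trials,
#'   the fraction of input variance carried by that stimulus, and its
#'   filter's half-width (bins).
#' @return A list of class `circuit_spec`.
#' @seealso [circuit_preset()] for ready-made configurations,
#'   [simulate_pair()], [simulate_trials()].
#' @export
circuit_spec <- function(connection = c("none", "static", "dynamic"),
                         epsilon = 0, theta = 1, delay_star = 4L,
                         filter_peak_delay = 4L, filter_half_width = 3,
                         input_mode = input_modes, shared_corr = 0,
                         n_samples = 2^16, seed = 1,
                         n_trials = NULL, trial_length = NULL,
                         frozen_stimulus = FALSE, stimulus_weight = 0.5,
                         stimulus_half_width = 10) {
  connection <- match.arg(connection)
  input_mode <- match.arg(input_mode)
  stopifnot(epsilon >= 0, shared_corr >= 0, shared_corr <= 1, n_samples >= 1,
            is.numeric(theta), length(theta) == 1L)
  if (connection == "static" && !is_wholenumber(delay_star)) {
    stop("`delay_star` must be an integer number of bins", call. = FALSE)
  }
  if (input_mode %in% c("independent_white", "correlated_input_on_Y") && shared_corr != 0) {
    stop("`shared_corr` requires a shared input mode", call. = FALSE)
  }
  structure(list(connection = connection, epsilon = epsilon, theta = theta,
                 delay_star = as.integer(delay_star),
                 filter_peak_delay = as.integer(filter_peak_delay),
                 filter_half_width = filter_half_width,
                 input_mode = input_mode, shared_corr = shared_corr,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 n_trials = n_trials, trial_length = trial_length,
                 frozen_stimulus = frozen_stimulus,
                 stimulus_weight = stimulus_weight,
                 stimulus_half_width = stimulus_half_width),
            class = "circuit_spec")
}

#' Ready-made circuit configurations
#'
#' Four standard two-neuron scenarios used throughout the documentation and
#' tests:
#' \describe{
#'   \item{`"dynamic"`}{independent white inputs; Y drives X through a strong
#'     dynamic connection (Gaussian kernel, peak delay 4 bins, half-width 3,
#'     `epsilon = 0.5`). Both the cross-correlation and the IMI profile are
#'     broad: the width reflects real connection dynamics.}
#'   \item{`"static_correlated"`}{Y's input is temporally correlated
#'     (zero-peak kernel, half-width 3), X's input white; strong static
#'     connection at 4 bins (`epsilon = 0.5`). The cross-correlation is still
#'     broad (input autocorrelation), but the IMI profile is sharp at 4.}
#'   \item{`"weak_shared"`}{both inputs share a temporally correlated source
#'     (source correlation 0.5) and a weak static connection at 3 bins
#'     (`epsilon = 0.25`) links Y to X: the connection is masked in the
#'     cross-correlation but isolated by the IMI.}
#'   \item{`"weak_shared_white"`}{as `"weak_shared"` but the shared input is
#'     white: its effect cannot be conditioned out and the IMI shows two
#'     peaks, at delay 0 (shared input) and at the connection delay 3.}
#' }
#'
#' @param preset one of the four names above.
#' @param n_samples,seed passed through to [circuit_spec()].
#' @return A `circuit_spec`.
#' @export
circuit_preset <- function(preset = c("dynamic", "static_correlated",
                                      "weak_shared", "weak_shared_white"),
                           n_samples = 2^20, seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    dynamic = circuit_spec("dynamic", epsilon = 0.5, theta = 1,
                           filter_peak_delay = 4L, filter_half_width = 3,
                           input_mode = "independent_white",
                           n_samples = n_samples, seed = seed),
    static_correlated = circuit_spec("static", epsilon = 0.5, theta = 1,
                                     delay_star = 4L, filter_half_width = 3,
                                     input_mode = "correlated_input_on_Y",
                                     n_samples = n_samples, seed = seed),
    weak_shared = circuit_spec("static", epsilon = 0.25, theta = 1,
                               delay_star = 3L, filter_half_width = 3,
                               input_mode = "shared_correlated", shared_corr = 0.5,
                               n_samples = n_samples, seed = seed),
    weak_shared_white = circuit_spec("static", epsilon = 0.25, theta = 1,
                                     delay_star = 3L,
                                     input_mode = "shared_white", shared_corr = 0.5,
                                     n_samples = n_samples, seed = seed))
}

# Causal convolution of `v` with kernel `g` (g[1] at lag 0); leading bins
# where the kernel overruns the start are computed on the zero-padded past.
causal_convolve <- function(v, g) {
  out <- stats::filter(c(rep(0, length(g) - 1L), v), g, method = "convolution",
                       sides = 1)
  as.numeric(out[length(g):(length(g) - 1L + length(v))])
}

# Temporally correlated unit-variance input: white noise smoothed with a
# symmetric Gaussian kernel peaked at lag zero, rescaled by the exact filter
# norm. Causality is immaterial for noise shaping, and a two-sided kernel
# gives the smooth (slow) autocorrelation that windowed conditioning on past
# and future can predict; a one-sided kernel would leave a fast edge at lag
# zero that no finite window conditions out.
correlate_input <- function(e, half_width) {
  sigma <- half_width / sqrt(2 * log(2))
  K <- as.integer(ceiling(4 * sigma))
  g <- exp(-((-K):K)^2 / (2 * sigma^2))
  out <- stats::filter(c(rep(0, K), e, rep(0, K)), g, method = "convolution",
                       sides = 2)
  as.numeric(out[(K + 1L):(K + length(e))]) / sqrt(sum(g^2))
}

#' Simulate one pair of spike trains
#'
#' Draws the two Gaussian noise sources (with correlation `shared_corr` in
#' the shared modes), applies the input filtering prescribed by
#' `input_mode`, thresholds Y, forms the drive from Y prescribed by the
#' connection type, and thresholds X. Reproducible bit-for-bit from
#' `spec$seed`.
#'
#' @param spec a [circuit_spec()] or [circuit_preset()].
#' @return A list with elements `x` and `y` (`binned_train` vectors of
#'   length `spec$n_samples`).
#' @examples
#' pair <- simulate_pair(circuit_preset("static_correlated", n_samples = 2^14))
#' mean(pair$y)  # close to 1 - pnorm(1)
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  with_seed(spec$seed, {
    N <- spec$n_samples
    z1 <- stats::rnorm(N)
    z2 <- stats::rnorm(N)
    rho <- spec$shared_corr
    e_y <- z1
    e_x <- if (spec$input_mode %in% c("shared_correlated", "shared_white")) {
      rho * z1 + sqrt(1 - rho^2) * z2
    } else {
      z2
    }
    hw <- spec$filter_half_width
    s_y <- switch(spec$input_mode,
                  independent_white = e_y,
                  shared_white = e_y,
                  correlated_input_on_Y = correlate_input(e_y, hw),
                  shared_correlated = correlate_input(e_y, hw))
    s_x <- switch(spec$input_mode,
                  independent_white = e_x,
                  shared_white = e_x,
                  correlated_input_on_Y = e_x,
                  shared_correlated = correlate_input(e_x, hw))
    y <- as.integer(s_y >= spec$theta)
    drive <- switch(spec$connection,
                    none = 0,
                    static = c(rep(0L, spec$delay_star),
                               y[seq_len(N - spec$delay_star)]),
                    dynamic = causal_convolve(
                      y, gaussian_filter(spec$filter_peak_delay, hw)))
    x <- as.integer(s_x + spec$epsilon * drive >= spec$theta)
    list(x = new_binned_train(x), y = new_binned_train(y))
  })
}

#' Simulate a repeated-trial experiment
#'
#' One slow shared Gaussian stimulus realization is drawn once and frozen
#' across all trials (the repeated-stimulus design); each trial adds
#' independent noise to both neurons and applies the connection within the
#' trial. Each neuron's input is
#' `sqrt(w) * stimulus + sqrt(1 - w) * trial_noise` with
#' `w = spec$stimulus_weight`, both components unit variance, so the
#' marginal spike probability stays `1 - pnorm(theta)`. The stimulus is
#' white noise filtered with a zero-peak Gaussian kernel of half-width
#' `spec$stimulus_half_width` bins, making its correlations slow relative to
#' the bin size — the regime in which signal IMI is expected to vanish while
#' the signal correlation is broad.
#'
#' @param spec a [circuit_spec()] with `n_trials >= 2`, `trial_length` set
#'   and `frozen_stimulus = TRUE`.
#' @return A [trial_set()].
#' @export
simulate_trials <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (is.null(spec$n_trials) || spec$n_trials < 2L) {
    stop("`n_trials` must be >= 2 for a trial simulation", call. = FALSE)
  }
  if (is.null(spec$trial_length)) stop("`trial_length` must be set", call. = FALSE)
  if (!isTRUE(spec$frozen_stimulus)) {
    stop("signal/noise analyses require `frozen_stimulus = TRUE`", call. = FALSE)
  }
  w <- spec$stimulus_weight
  stopifnot(w >= 0, w <= 1)
  with_seed(spec$seed, {
    L <- as.integer(spec$trial_length)
    nt <- as.integer(spec$n_trials)
    u <- correlate_input(stats::rnorm(L), spec$stimulus_half_width)
    xm <- matrix(0L, nt, L); ym <- matrix(0L, nt, L)
    rho <- spec$shared_corr
    hw <- spec$filter_half_width
    for (i in seq_len(nt)) {
      z1 <- stats::rnorm(L); z2 <- stats::rnorm(L)
      e_y <- z1
      e_x <- if (spec$input_mode %in% c("shared_correlated", "shared_white")) {
        rho * z1 + sqrt(1 - rho^2) * z2
      } else {
        z2
      }
      if (spec$input_mode %in% c("correlated_input_on_Y", "shared_correlated")) {
        e_y <- correlate_input(e_y, hw)
      }
      if (spec$input_mode == "shared_correlated") e_x <- correlate_input(e_x, hw)
      s_y <- sqrt(w) * u + sqrt(1 - w) * e_y
      s_x <- sqrt(w) * u + sqrt(1 - w) * e_x
      yi <- as.integer(s_y >= spec$theta)
      drive <- switch(spec$connection,
                      none = 0,
                      static = c(rep(0L, spec$delay_star),
                                 yi[seq_len(L - spec$delay_star)]),
                      dynamic = causal_convolve(
                        yi, gaussian_filter(spec$filter_peak_delay, hw)))
      xm[i, ] <- as.integer(s_x + spec$epsilon * drive >= spec$theta)
      ym[i, ] <- yi
    }
    trial_set(xm, ym)
  })
}
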