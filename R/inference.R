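# Bootstrap confidence intervals and shuffle-based significance thresholds.
# Resampling always operates on the aligned triples (X[n], Y[n-delta],
# V_delta[n]) after the conditioning vectors have been formed, so the
# temporal dependencies captured by the words are preserved.

#' Bootstrap settings
#'
#' @param n_resamples number of bootstrap resamples (>= 2; default 100).
#' @param seed integer seed for reproducible resampling, or `NULL`.
#' @param mode `"confidence"` (resample whole triples with replacement) or
#'   `"significance"` (resample Y separately from the (X, V) pairs).
#' @param shuffle for significance mode: `"permute"` (without replacement,
#'   default) or `"resample"` (with replacement).
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_resamples = 100, seed = NULL,
                             mode = c("confidence", "significance"),
                             shuffle = c("permute", "resample")) {
  mode <- match.arg(mode); shuffle <- match.arg(shuffle)
  if (!is_wholenumber(n_resamples) || n_resamples < 2) {
    stop("`n_resamples` must be an integer >= 2", call. = FALSE)
  }
  structure(list(n_resamples = as.integer(n_resamples), seed = seed,
                 mode = mode, shuffle = shuffle),
            class = "bootstrap_config")
}

# Measure evaluated on aligned samples; used by both bootstrap procedures.
# measure is one of "imi", "normalized_imi", "past_only_imi" (identical here:
# the past-only variant differs only in how the words were built),
# "cross_correlation".
eval_aligned_measure <- function(measure, tgt, ctx, yb, Kc, bias_correct) {
  if (measure == "cross_correlation") {
    xs <- tgt - 1L
    if (stats::sd(xs) == 0 || stats::sd(yb) == 0) return(NA_real_)
    return(stats::cor(xs, yb))
  }
  res <- imi_from_aligned(tgt, ctx, yb, Kc, bias_correct)
  if (measure == "normalized_imi") normalize_di(res$di, res$h_v) else res$di
}

# Confidence interval from resampling whole triples with replacement;
# degenerate resamples (NA measure, e.g. a constant context/train for the
# correlation measure) are skipped and redrawn, capped at 10x the requested
# number.
aligned_boot_ci <- function(measure, tgt, ctx, yb, Kc, bias_correct, n_resamples) {
  n <- length(tgt)
  vals <- numeric(n_resamples)
  draws <- 0L; cap <- 10L * n_resamples; got <- 0L
  while (got < n_resamples && draws < cap) {
    draws <- draws + 1L
    idx <- sample.int(n, n, replace = TRUE)
    v <- eval_aligned_measure(measure, tgt[idx], ctx[idx], yb[idx], Kc, bias_correct)
    if (is.na(v)) next
    got <- got + 1L
    vals[got] <- v
  }
  if (got < 2L) stop("bootstrap failed: resamples persistently degenerate", call. = FALSE)
  vals <- vals[seq_len(got)]
  m <- mean(vals); s <- stats::sd(vals)
  c(low = m - 2 * s, high = m + 2 * s)
}

# Null distribution from resampling Y separately from (X, V); returns the
# significance threshold mean + 2 SD. For the IMI measures H(X|V) is
# unchanged by the shuffle and is computed once.
aligned_sig_threshold <- function(measure, tgt, ctx, yb, Kc, bias_correct,
                                  n_resamples, shuffle = "permute") {
  n <- length(tgt)
  vals <- numeric(n_resamples)
  if (measure == "cross_correlation") {
    xs <- tgt - 1L
    if (stats::sd(xs) == 0 || stats::sd(yb) == 0) return(0)
    for (b in seq_len(n_resamples)) {
      yp <- if (shuffle == "permute") yb[sample.int(n, n)] else yb[sample.int(n, n, replace = TRUE)]
      v <- stats::cor(xs, yp)
      vals[b] <- if (is.na(v)) 0 else v
    }
  } else {
    h_v <- cond_h_codes(tgt, 2L, ctx, Kc, bias_correct)$value
    for (b in seq_len(n_resamples)) {
      yp <- if (shuffle == "permute") yb[sample.int(n, n)] else yb[sample.int(n, n, replace = TRUE)]
      ctx_y <- (ctx - 1L) * 2L + yp + 1L
      h_vy <- cond_h_codes(tgt, 2L, ctx_y, 2L * Kc, bias_correct)$value
      di <- h_v - h_vy
      # null draws are not clipped: the shuffle leaves H(X|V) unchanged, so
      # the normalized null is the raw null over a common positive constant,
      # and clipping would shrink the null spread and inflate the flag rate
      vals[b] <- if (measure == "normalized_imi") {
        if (h_v < 1e-9) 0 else di / h_v
      } else {
        di
      }
    }
  }
  mean(vals) + 2 * stats::sd(vals)
}

# Shared driver for the profile-level inference columns.
aligned_inference <- function(tgt, ctx, yb, Kc, bias_correct, normalized,
                              ci, significance, n_resamples, shuffle) {
  measure <- if (normalized) "normalized_imi" else "imi"
  out <- list()
  if (ci) {
    out$ci <- aligned_boot_ci(measure, tgt, ctx, yb, Kc, bias_correct, n_resamples)
  }
  if (significance) {
    out$threshold <- aligned_sig_threshold(measure, tgt, ctx, yb, Kc, bias_correct,
                                           n_resamples, shuffle)
  }
  out
}

# Build aligned triples for the exported single-delay interfaces.
aligned_triples <- function(x, y, delta, omega, measure) {
  past_only <- measure == "past_only_imi"
  cw <- build_conditioning_words(x, y, delta, omega, past_only = past_only)
  list(tgt = cw$x_s + 1L, ctx = cw$word + 1L, yb = cw$y_s,
       Kc = as.integer(2^cw$bits))
}

measure_choices <- c("imi", "normalized_imi", "past_only_imi", "cross_correlation")

#' Bootstrap confidence interval for a measure at one delay
#'
#' Forms the aligned triples `(X[n], Y[n - delta], V_delta[n])` once, then
#' resamples whole triples with replacement `n_resamples` times and
#' recomputes the measure on each resample. The interval is the mean +/- 2
#' standard deviations of the resampled values.
#'
#' @param x,y equal-length 0/1 trains.
#' @param delta integer delay (bins).
#' @param omega conditioning-window half-length (bins).
#' @param measure which measure to resample: `"imi"`, `"normalized_imi"`,
#'   `"past_only_imi"` or `"cross_correlation"`.
#' @param config a [bootstrap_config()].
#' @param bias_correct apply quadratic-extrapolation correction to the
#'   entropy terms of the IMI measures.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(x, y, delta, omega = 2, measure = measure_choices,
                         config = bootstrap_config(), bias_correct = TRUE) {
  measure <- match.arg(measure)
  tr <- aligned_triples(x, y, delta, omega, measure)
  with_seed(config$seed,
            aligned_boot_ci(measure, tr$tgt, tr$ctx, tr$yb, tr$Kc, bias_correct,
                            config$n_resamples))
}

#' Shuffle-based significance threshold for a measure at one delay
#'
#' Resamples `Y[n - delta]` separately from the `(X[n], V_delta[n])` pairs
#' (a permutation by default, preserving the Y marginal exactly), which
#' removes the dependency between X and Y while keeping each train's internal
#' structure. The threshold is the mean + 2 standard deviations of the
#' measure over the null resamples; an observed value above it is considered
#' significantly different from zero.
#'
#' @inheritParams bootstrap_ci
#' @return A single number, the significance threshold.
#' @export
significance_threshold <- function(x, y, delta, omega = 2, measure = measure_choices,
                                   config = bootstrap_config(mode = "significance"),
                                   bias_correct = TRUE) {
  measure <- match.arg(measure)
  tr <- aligned_triples(x, y, delta, omega, measure)
  with_seed(config$seed,
            aligned_sig_threshold(measure, tr$tgt, tr$ctx, tr$yb, tr$Kc,
                                  bias_correct, config$n_resamples, config$shuffle))
}
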