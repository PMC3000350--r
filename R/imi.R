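# Incremental mutual information: the additional reduction in the entropy of
# X[n] obtained by observing Y[n - delta], after conditioning on the windowed
# past and future of both trains.

# Per-delay IMI from aligned samples. tgt: X[n] codes in 1..2; ctx: word
# codes in 1..Kc; yb: Y[n - delta] bits (0/1).
# Returns dI = H(X|V) - H(X|V, Y), the denominator H(X|V), and raw
# (uncorrected) versions of both.
imi_from_aligned <- function(tgt, ctx, yb, Kc, bias_correct) {
  h_v <- cond_h_codes(tgt, 2L, ctx, Kc, bias_correct)
  ctx_y <- (ctx - 1L) * 2L + yb + 1L
  h_vy <- cond_h_codes(tgt, 2L, ctx_y, 2L * Kc, bias_correct)
  list(di = h_v$value - h_vy$value, h_v = h_v$value,
       di_raw = h_v$raw - h_vy$raw, h_v_raw = h_v$raw)
}

# Normalization: dI as a fraction of its maximum possible value H(X|V);
# zero when the denominator vanishes, clipped to [0, 1].
normalize_di <- function(di, h_v, tol = 1e-9) {
  if (h_v < tol) return(0)
  clip01(di / h_v)
}

imi_profile <- function(x, y, deltas, omega, bias_correct, normalized, past_only,
                        ci, significance, n_resamples, seed, shuffle) {
  x <- as_binary_vector(x, "x"); y <- as_binary_vector(y, "y")
  deltas <- sort(unique(as.integer(deltas)))
  nd <- length(deltas)
  vals <- numeric(nd); ns <- integer(nd)
  ci_lo <- rep(NA_real_, nd); ci_hi <- rep(NA_real_, nd); sig <- rep(NA_real_, nd)
  want_inference <- isTRUE(ci) || isTRUE(significance)
  for (i in seq_len(nd)) {
    d <- deltas[i]
    cw <- build_conditioning_words(x, y, d, omega, past_only = past_only)
    nv <- length(cw$word)
    if (bias_correct && nv < 8L) {
      stop(sprintf(paste0(
        "only %d valid samples at delta = %d; quadratic extrapolation needs >= 8 ",
        "(train length N >= %d for this delta and omega)"),
        nv, d, 8L + 2L * as.integer(omega) + abs(d)), call. = FALSE)
    }
    tgt <- cw$x_s + 1L
    ctx <- cw$word + 1L
    Kc <- as.integer(2^cw$bits)
    res <- imi_from_aligned(tgt, ctx, cw$y_s, Kc, bias_correct)
    vals[i] <- if (normalized) normalize_di(res$di, res$h_v) else res$di
    ns[i] <- nv
    if (want_inference) {
      boot_seed <- if (is.null(seed)) NULL else seed + i
      inf <- with_seed(boot_seed, aligned_inference(
        tgt, ctx, cw$y_s, Kc, bias_correct, normalized,
        ci = ci, significance = significance,
        n_resamples = n_resamples, shuffle = shuffle))
      if (ci) { ci_lo[i] <- inf$ci[1]; ci_hi[i] <- inf$ci[2] }
      if (significance) sig[i] <- inf$threshold
    }
  }
  df <- tibble::tibble(delta = deltas, value = vals, n = ns)
  if (ci) { df$ci_low <- ci_lo; df$ci_high <- ci_hi }
  if (significance) df$sig_threshold <- sig
  measure <- paste0(if (normalized) "normalized_" else "",
                    if (past_only) "past_only_" else "", "imi")
  new_delay_profile(df, measure = measure,
                    units = if (normalized) "fraction" else "bits",
                    omega = as.integer(omega), bias_corrected = bias_correct)
}

#' Incremental mutual information profile
#'
#' For each delay \eqn{\delta} on the grid, the incremental mutual
#' information \eqn{\Delta I(\delta) = H(X[n] \mid V_\delta) -
#' H(X[n] \mid V_\delta, Y[n-\delta])}: the additional reduction in the
#' entropy of `X[n]` from observing `Y[n - delta]` after conditioning on the
#' windowed past and future of both trains (the conditioning vector
#' \eqn{V_\delta}, `4 * omega` binary variables). Because the temporal
#' dependencies within each train are conditioned out first, the profile
#' reflects the strength and dynamics of the direct dependency between the
#' trains rather than their individual autocorrelations.
#'
#' Entropies are estimated by the plug-in estimator, bias-corrected by
#' quadratic extrapolation when `bias_correct = TRUE` (the default, as the
#' conditioning words span a large alphabet). Valid-sample sets differ across
#' delays (edge samples are dropped, not padded); the per-delay count is
#' returned in column `n`.
#'
#' @param x,y equal-length 0/1 spike trains (plain vectors or
#'   `binned_train`).
#' @param deltas integer delay grid (default -10..10). `value` at delay
#'   \eqn{\delta} measures the influence of `y` on `x` at lag \eqn{\delta}.
#' @param omega conditioning-window half-length in bins (>= 1).
#' @param bias_correct apply quadratic-extrapolation bias correction to every
#'   entropy term.
#' @param ci if `TRUE`, append a bootstrap confidence band (`ci_low`,
#'   `ci_high`): mean +/- 2 SD over `n_resamples` resamples of the aligned
#'   (X, Y, V) triples, drawn with replacement.
#' @param significance if `TRUE`, append a shuffle-based significance
#'   threshold (`sig_threshold`): mean + 2 SD of the measure under resampling
#'   of Y separately from (X, V), which destroys the X--Y dependency.
#' @param n_resamples bootstrap resamples (default 100).
#' @param seed integer seed making the resampling reproducible; the caller's
#'   RNG state is left untouched.
#' @param shuffle how the significance null resamples Y: `"permute"`
#'   (without replacement, preserving the marginal exactly; default) or
#'   `"resample"` (with replacement).
#' @return A `delay_profile` tibble (columns `delta`, `value`, `n`, plus
#'   inference columns when requested); units bits.
#' @seealso [normalized_imi()], [past_only_imi()], [cross_correlation()],
#'   [partial_cross_correlation()]
#' @examples
#' y <- rbinom(3000, 1, 0.5)
#' x <- c(0L, 0L, 0L, y[1:2997])  # x copies y at lag 3
#' imi(x, y, deltas = -5:5, omega = 1, bias_correct = FALSE)
#' @export
imi <- function(x, y, deltas = -10:10, omega = 2, bias_correct = TRUE,
                ci = FALSE, significance = FALSE, n_resamples = 100,
                seed = NULL, shuffle = c("permute", "resample")) {
  shuffle <- match.arg(shuffle)
  imi_profile(x, y, deltas, omega, bias_correct, normalized = FALSE,
              past_only = FALSE, ci = ci, significance = significance,
              n_resamples = n_resamples, seed = seed, shuffle = shuffle)
}

#' Normalized incremental mutual information
#'
#' The IMI expressed as a fraction of its maximum possible value:
#' \eqn{\tilde{\Delta I}(\delta) = \Delta I(\delta) / H(X[n] \mid V_\delta)},
#' the analogue of a partial correlation coefficient. Defined as 0 when the
#' denominator is below tolerance and clipped to \[0, 1\] (bias-corrected
#' estimates can stray slightly outside).
#'
#' @inheritParams imi
#' @return A `delay_profile` tibble, dimensionless values in \[0, 1\].
#' @export
normalized_imi <- function(x, y, deltas = -10:10, omega = 2, bias_correct = TRUE,
                           ci = FALSE, significance = FALSE, n_resamples = 100,
                           seed = NULL, shuffle = c("permute", "resample")) {
  shuffle <- match.arg(shuffle)
  imi_profile(x, y, deltas, omega, bias_correct, normalized = TRUE,
              past_only = FALSE, ci = ci, significance = significance,
              n_resamples = n_resamples, seed = seed, shuffle = shuffle)
}

#' Past-only incremental mutual information
#'
#' The transfer-entropy-style variant: the conditioning word contains only
#' the past of both trains (`X[n-omega..n-1]` and
#' `Y[n-delta-omega..n-delta-1]`, `2 * omega` bits), not their futures. It
#' conditions out slow dependencies correctly for delays smaller than the
#' true connection delay but not for larger ones, which is why the full
#' (past + future) conditioning of [imi()] is the default measure.
#'
#' @inheritParams imi
#' @param normalized divide by the conditional entropy of `X[n]` given the
#'   past-only word (clipped to \[0, 1\]).
#' @return A `delay_profile` tibble.
#' @export
past_only_imi <- function(x, y, deltas = -10:10, omega = 2, bias_correct = TRUE,
                          normalized = FALSE, ci = FALSE, significance = FALSE,
                          n_resamples = 100, seed = NULL,
                          shuffle = c("permute", "resample")) {
  shuffle <- match.arg(shuffle)
  imi_profile(x, y, deltas, omega, bias_correct, normalized = normalized,
              past_only = TRUE, ci = ci, significance = significance,
              n_resamples = n_resamples, seed = seed, shuffle = shuffle)
}
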