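# Trial-based measures for repeated-stimulus designs: the dependency between
# two neurons is split into a stimulus-locked (signal) part, estimated across
# different trials, and the remaining within-trial (noise) part.

#' Bundle per-trial spike-train pairs
#'
#' @param x,y integer 0/1 matrices, one row per trial, one column per time
#'   bin; equal dimensions.
#' @param bin_width optional bin width in seconds (metadata).
#' @return A list of class `trial_set` with elements `x`, `y`, `n_trials`,
#'   `trial_length`.
#' @export
trial_set <- function(x, y, bin_width = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("`x` and `y` must have identical dimensions", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L) stop("empty trial set", call. = FALSE)
  storage.mode(x) <- "integer"; storage.mode(y) <- "integer"
  if (anyNA(x) || anyNA(y) || !all(x %in% c(0L, 1L)) || !all(y %in% c(0L, 1L))) {
    stop("trial matrices must contain only 0/1 values", call. = FALSE)
  }
  structure(list(x = x, y = y, n_trials = nrow(x), trial_length = ncol(x),
                 bin_width = bin_width),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d bins (mean rates %.3f / %.3f)\n",
              x$n_trials, x$trial_length, mean(x$x), mean(x$y)))
  invisible(x)
}

# Ordered trial pairs (i, j), i != j: all of them up to 50 trials, otherwise
# `max_pairs` seeded random draws.
trial_pairs <- function(n_trials, max_pairs = 2000, seed = 1) {
  if (n_trials < 2L) stop("signal/noise decomposition needs at least 2 trials", call. = FALSE)
  if (n_trials <= 50L) {
    g <- expand.grid(i = seq_len(n_trials), j = seq_len(n_trials))
    g <- g[g$i != g$j, , drop = FALSE]
    return(cbind(i = g$i, j = g$j))
  }
  with_seed(seed, {
    i <- sample.int(n_trials, max_pairs, replace = TRUE)
    j <- sample.int(n_trials - 1L, max_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    cbind(i = i, j = j)
  })
}

# Overlap range of 1-based sample indices n for a given delay.
overlap_range <- function(len, d) max(1L, 1L + d):min(len, len + d)

# Pearson correlation from pooled samples accumulated over trial pairs:
# for each pair (i, j) the x-part is X[i, n] and the y-part Y[j, n - d].
pooled_pair_cor <- function(xm, ym, pairs, d) {
  len <- ncol(xm)
  n <- overlap_range(len, d)
  sx <- sy <- sxx <- syy <- sxy <- 0; cnt <- 0
  for (r in seq_len(nrow(pairs))) {
    xs <- xm[pairs[r, 1L], n]
    ys <- ym[pairs[r, 2L], n - d]
    sx <- sx + sum(xs); sy <- sy + sum(ys)
    sxx <- sxx + sum(xs * xs); syy <- syy + sum(ys * ys)
    sxy <- sxy + sum(xs * ys); cnt <- cnt + length(n)
  }
  cov <- sxy / cnt - (sx / cnt) * (sy / cnt)
  vx <- sxx / cnt - (sx / cnt)^2
  vy <- syy / cnt - (sy / cnt)^2
  if (vx <= 0 || vy <= 0) {
    stop(sprintf("constant train over the overlap at delta = %d", d), call. = FALSE)
  }
  cov / sqrt(vx * vy)
}

#' Signal (shift-predictor) correlation
#'
#' The correlation between `X` on trial i and `Y` on trial j at each delay,
#' pooled over ordered trial pairs with i != j. Shuffling the trial pairing
#' keeps only the dependency locked to the repeated stimulus, so this is the
#' classical shift-predictor. All ordered pairs are used up to 50 trials;
#' beyond that, `max_pairs` seeded random pairs.
#'
#' @param trials a [trial_set()].
#' @param deltas integer delay grid.
#' @param max_pairs cap on sampled ordered pairs when `n_trials > 50`.
#' @param seed seed for pair sampling (only used when pairs are sampled).
#' @return A `delay_profile` tibble.
#' @export
signal_correlation <- function(trials, deltas = -10:10, max_pairs = 2000, seed = 1) {
  stopifnot(inherits(trials, "trial_set"))
  pairs <- trial_pairs(trials$n_trials, max_pairs, seed)
  deltas <- sort(unique(as.integer(deltas)))
  vals <- vapply(deltas, function(d) pooled_pair_cor(trials$x, trials$y, pairs, d),
                 numeric(1))
  new_delay_profile(tibble::tibble(delta = deltas, value = vals),
                    measure = "signal_correlation", units = "dimensionless")
}

#' Within-trial (total) cross-correlation of a trial set
#'
#' The correlation between `X` and `Y` on the same trial at each delay,
#' pooled over trials; the sum of the signal and noise components.
#'
#' @inheritParams signal_correlation
#' @return A `delay_profile` tibble.
#' @export
trial_cross_correlation <- function(trials, deltas = -10:10) {
  stopifnot(inherits(trials, "trial_set"))
  pairs <- cbind(i = seq_len(trials$n_trials), j = seq_len(trials$n_trials))
  deltas <- sort(unique(as.integer(deltas)))
  vals <- vapply(deltas, function(d) pooled_pair_cor(trials$x, trials$y, pairs, d),
                 numeric(1))
  new_delay_profile(tibble::tibble(delta = deltas, value = vals),
                    measure = "trial_cross_correlation", units = "dimensionless")
}

#' Noise correlation
#'
#' The within-trial correlation minus the signal correlation at each delay:
#' the dependency carried by the trial-to-trial variable part of the
#' responses (connections and shared network/cellular mechanisms), after the
#' stimulus-locked component has been removed.
#'
#' @inheritParams signal_correlation
#' @return A `delay_profile` tibble.
#' @export
noise_correlation <- function(trials, deltas = -10:10, max_pairs = 2000, seed = 1) {
  tot <- trial_cross_correlation(trials, deltas)
  sig <- signal_correlation(trials, deltas, max_pairs, seed)
  new_delay_profile(tibble::tibble(delta = tot$delta, value = tot$value - sig$value),
                    measure = "noise_correlation", units = "dimensionless")
}

# ---- trial-based IMI -------------------------------------------------------

# Aligned per-trial word/sample matrices at one delay. All trials share the
# valid-index set, so words and samples pool row-wise.
trial_aligned <- function(trials, d, omega) {
  nt <- trials$n_trials
  cws <- lapply(seq_len(nt), function(i) {
    build_conditioning_words(trials$x[i, ], trials$y[i, ], d, omega)
  })
  list(tgt = lapply(cws, function(cw) cw$x_s + 1L),
       ctx = lapply(cws, function(cw) cw$word + 1L),
       yb = lapply(cws, function(cw) cw$y_s),
       Kc = as.integer(2^cws[[1L]]$bits),
       n_valid = length(cws[[1L]]$word))
}

# Trial-based IMI terms at one delay:
#   h_v    = H(X^i[n] | V^i)                pooled over trials
#   h_sig  = H(X^i[n] | V^i, Y^j[n-d])      pooled over ordered pairs j != i
#   h_tot  = H(X^i[n] | V^i, Y^i[n-d])      pooled over trials
# signal IMI = h_v - h_sig; noise IMI = h_sig - h_tot; total = h_v - h_tot,
# so signal + noise = total exactly, term by term.
trial_imi_terms <- function(trials, d, omega, bias_correct, pairs) {
  al <- trial_aligned(trials, d, omega)
  nt <- trials$n_trials
  tgt_pool <- unlist(al$tgt, use.names = FALSE)
  ctx_pool <- unlist(al$ctx, use.names = FALSE)
  Kc <- al$Kc
  h_v <- cond_h_codes(tgt_pool, 2L, ctx_pool, Kc, bias_correct)$value
  ctx_tot <- (ctx_pool - 1L) * 2L + unlist(al$yb, use.names = FALSE) + 1L
  h_tot <- cond_h_codes(tgt_pool, 2L, ctx_tot, 2L * Kc, bias_correct)$value
  tgt_pair <- unlist(al$tgt[pairs[, 1L]], use.names = FALSE)
  ctx_pair <- (unlist(al$ctx[pairs[, 1L]], use.names = FALSE) - 1L) * 2L +
    unlist(al$yb[pairs[, 2L]], use.names = FALSE) + 1L
  h_sig <- cond_h_codes(tgt_pair, 2L, ctx_pair, 2L * Kc, bias_correct)$value
  list(h_v = h_v, h_sig = h_sig, h_tot = h_tot, n_valid = al$n_valid)
}

trial_imi_profile <- function(trials, deltas, omega, bias_correct, normalized,
                              which, max_pairs, seed) {
  stopifnot(inherits(trials, "trial_set"))
  if (which != "total" && trials$n_trials < 2L) {
    stop("signal/noise decomposition needs at least 2 trials", call. = FALSE)
  }
  deltas <- sort(unique(as.integer(deltas)))
  pairs <- if (which == "total") {
    cbind(i = seq_len(trials$n_trials), j = seq_len(trials$n_trials))
  } else {
    trial_pairs(trials$n_trials, max_pairs, seed)
  }
  vals <- numeric(length(deltas)); ns <- integer(length(deltas))
  for (k in seq_along(deltas)) {
    tm <- trial_imi_terms(trials, deltas[k], omega, bias_correct, pairs)
    di <- switch(which,
                 signal = tm$h_v - tm$h_sig,
                 noise = tm$h_sig - tm$h_tot,
                 total = tm$h_v - tm$h_tot)
    vals[k] <- if (normalized) normalize_di(di, tm$h_v) else di
    ns[k] <- tm$n_valid
  }
  new_delay_profile(tibble::tibble(delta = deltas, value = vals, n = ns),
                    measure = paste0(if (normalized) "normalized_" else "",
                                     which, "_imi"),
                    units = if (normalized) "fraction" else "bits",
                    omega = as.integer(omega), bias_corrected = bias_correct)
}

#' Signal IMI
#'
#' The incremental mutual information between `X` on trial i and `Y` on a
#' different trial j: the reduction in the entropy of `X^i[n]` from observing
#' `Y^j[n - delta]` beyond what the within-trial conditioning vector `V^i`
#' already provides. Captures only the stimulus-locked dependency; with slow
#' stimulus correlations and fine bins it is close to zero even when the
#' signal correlation is broad, because the within-trial context already
#' predicts the slow component.
#'
#' @param trials a [trial_set()].
#' @param deltas integer delay grid.
#' @param omega conditioning-window half-length (bins).
#' @param bias_correct apply quadratic-extrapolation bias correction.
#' @param normalized divide by the conditioning entropy `H(X|V)` and clip to
#'   \[0, 1\].
#' @param max_pairs,seed trial-pair sampling rule (all ordered pairs up to 50
#'   trials, else `max_pairs` seeded draws).
#' @return A `delay_profile` tibble.
#' @export
signal_imi <- function(trials, deltas = -10:10, omega = 2, bias_correct = TRUE,
                       normalized = FALSE, max_pairs = 2000, seed = 1) {
  trial_imi_profile(trials, deltas, omega, bias_correct, normalized,
                    which = "signal", max_pairs = max_pairs, seed = seed)
}

#' Noise IMI
#'
#' The difference between the trial-wise total IMI and the signal IMI:
#' \eqn{H(X^i[n] \mid V^i, Y^j[n-\delta]) - H(X^i[n] \mid V^i,
#' Y^i[n-\delta])} pooled over ordered pairs, the dependency carried by the
#' trial-variable part of the responses. For a connection driven by
#' within-trial activity this retains the connection peak.
#'
#' @inheritParams signal_imi
#' @return A `delay_profile` tibble.
#' @export
noise_imi <- function(trials, deltas = -10:10, omega = 2, bias_correct = TRUE,
                      normalized = FALSE, max_pairs = 2000, seed = 1) {
  trial_imi_profile(trials, deltas, omega, bias_correct, normalized,
                    which = "noise", max_pairs = max_pairs, seed = seed)
}

#' Trial-wise total IMI
#'
#' The within-trial IMI pooled over trials; equals signal IMI + noise IMI at
#' every delay by construction.
#'
#' @inheritParams signal_imi
#' @return A `delay_profile` tibble.
#' @export
trial_imi <- function(trials, deltas = -10:10, omega = 2, bias_correct = TRUE,
                      normalized = FALSE) {
  trial_imi_profile(trials, deltas, omega, bias_correct, normalized,
                    which = "total", max_pairs = 0, seed = 1)
}
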