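# Linear comparator measures: cross-correlation and partial
# cross-correlation over a grid of integer delays.

#' Cross-correlation function of two binned trains
#'
#' The Pearson correlation coefficient between `X[n]` and `Y[n - delta]`
#' over the overlapping range, for each delay on the grid. This is the
#' classical delay-resolved measure of total linear dependency; it cannot
#' separate connection dynamics from temporal correlations within each train.
#'
#' @param x,y equal-length 0/1 trains (plain vectors or `binned_train`).
#' @param deltas integer delay grid (default -10..10).
#' @return A `delay_profile` tibble with columns `delta`, `value`, `n`.
#' @export
cross_correlation <- function(x, y, deltas = -10:10) {
  x <- as_binary_vector(x, "x"); y <- as_binary_vector(y, "y")
  if (length(x) != length(y)) stop("`x` and `y` must have the same length", call. = FALSE)
  deltas <- sort(unique(as.integer(deltas)))
  N <- length(x)
  vals <- numeric(length(deltas)); ns <- integer(length(deltas))
  for (i in seq_along(deltas)) {
    d <- deltas[i]
    n <- max(1L, 1L + d):min(N, N + d)
    xs <- x[n]; ys <- y[n - d]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      stop(sprintf("constant train over the overlap at delta = %d (zero standard deviation)", d),
           call. = FALSE)
    }
    vals[i] <- stats::cor(xs, ys)
    ns[i] <- length(n)
  }
  new_delay_profile(tibble::tibble(delta = deltas, value = vals, n = ns),
                    measure = "cross_correlation", units = "dimensionless")
}

#' Partial cross-correlation function
#'
#' The correlation between `X[n]` and `Y[n - delta]` after the windowed past
#' and future of both trains (the conditioning variables, taken as real
#' regressors) have been regressed out of each by least squares. The linear
#' analogue of incremental mutual information: the residual correlation
#' measures the dependency not explained by the temporal context.
#'
#' @inheritParams cross_correlation
#' @param omega window half-length in bins; `omega = 0` conditions on nothing
#'   and reduces to [cross_correlation()] over the same sample set.
#' @return A `delay_profile` tibble with columns `delta`, `value`, `n`.
#' @export
partial_cross_correlation <- function(x, y, deltas = -10:10, omega = 2) {
  x <- as_binary_vector(x, "x"); y <- as_binary_vector(y, "y")
  if (length(x) != length(y)) stop("`x` and `y` must have the same length", call. = FALSE)
  if (!is_wholenumber(omega) || omega < 0) stop("`omega` must be an integer >= 0", call. = FALSE)
  deltas <- sort(unique(as.integer(deltas)))
  omega <- as.integer(round(omega))
  vals <- numeric(length(deltas)); ns <- integer(length(deltas))
  for (i in seq_along(deltas)) {
    d <- deltas[i]
    wm <- window_matrix(x, y, d, max(omega, 0L))
    w <- if (omega == 0L) matrix(numeric(0), nrow = length(wm$n), ncol = 0) else wm$w
    z <- cbind(1, w)
    qz <- qr(z)
    if (qz$rank < ncol(z)) {
      warning(sprintf("collinear conditioning columns dropped at delta = %d", d), call. = FALSE)
    }
    rx <- qr.resid(qz, wm$x_s)
    ry <- qr.resid(qz, wm$y_s)
    vals[i] <- if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
      NA_real_
    } else {
      stats::cor(rx, ry)
    }
    ns[i] <- length(wm$n)
  }
  new_delay_profile(tibble::tibble(delta = deltas, value = vals, n = ns),
                    measure = "partial_cross_correlation", units = "dimensionless",
                    omega = omega)
}
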