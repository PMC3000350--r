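# Conditioning-vector construction: the discrete context of past and future
# bins of both trains around the sample pair (X[n], Y[n - delta]) whose
# dependency is being measured.

# Window offsets relative to the anchor, oldest first, anchor excluded.
# Full windows: (-omega..-1, +1..+omega); past-only: (-omega..-1).
window_offsets <- function(omega, past_only = FALSE) {
  if (omega < 1L) return(integer(0))
  if (past_only) -(omega:1) else c(-(omega:1), 1:omega)
}

# Valid 1-based sample indices n such that every window index of both trains
# lies inside [1, N]. The X-window is anchored on n, the Y-window on
# n - delta. Count is N - 2*omega - |delta| (full windows).
valid_sample_range <- function(n_bins, delta, omega) {
  lo <- max(omega + 1L, delta + omega + 1L)
  hi <- min(n_bins - omega, n_bins + delta - omega)
  if (lo > hi) return(integer(0))
  lo:hi
}

#' Build conditioning words for a pair of binned trains
#'
#' For each valid sample index `n`, forms the discrete context word made of
#' the windowed past and future of `x` around `n` (excluding `X[n]`) and of
#' `y` around `n - delta` (excluding `Y[n - delta]`), together with the
#' aligned scalar samples `X[n]` and `Y[n - delta]`. Words are packed into a
#' single integer code with a fixed bit order — X-past oldest first, then
#' X-future, then Y-past oldest first, then Y-future — so entropy tables are
#' reproducible. Samples whose windows overrun either end of the trains are
#' dropped; the number of valid samples is `N - 2 * omega - |delta|` for full
#' windows.
#'
#' @param x,y equal-length 0/1 trains (`binned_train` or plain vectors).
#' @param delta integer delay in bins; the context is relative to the pair
#'   `(X[n], Y[n - delta])`.
#' @param omega window half-length in bins (>= 1); full words carry
#'   `4 * omega` bits, past-only words `2 * omega` bits.
#' @param past_only if `TRUE`, condition only on the past of both trains
#'   (the transfer-entropy-style context).
#' @return A list of class `conditioning_words` with elements `word` (integer
#'   codes in `[0, 2^bits)`), `x_s` and `y_s` (the aligned scalar samples),
#'   `n` (the valid 1-based sample indices), `delta`, `omega`, `bits`,
#'   `past_only`.
#' @export
build_conditioning_words <- function(x, y, delta, omega, past_only = FALSE) {
  x <- as_binary_vector(x, "x")
  y <- as_binary_vector(y, "y")
  if (length(x) != length(y)) stop("`x` and `y` must have the same length", call. = FALSE)
  if (!is_wholenumber(delta)) stop("`delta` must be a single integer", call. = FALSE)
  if (!is_wholenumber(omega) || omega < 1) stop("`omega` must be an integer >= 1", call. = FALSE)
  delta <- as.integer(round(delta)); omega <- as.integer(round(omega))
  bits <- if (past_only) 2L * omega else 4L * omega
  # joint codes with the target and Y sample add 2 more bits; keep the full
  # table addressable by tabulate()
  if (bits + 2L > 24L) stop("`omega` too large: word tables would exceed 2^24 states", call. = FALSE)
  n <- valid_sample_range(length(x), delta, omega)
  if (length(n) == 0L) {
    stop(sprintf("trains too short: no sample has complete windows (need N > %d)",
                 2L * omega + abs(delta)), call. = FALSE)
  }
  offs <- window_offsets(omega, past_only)
  word <- numeric(length(n))
  for (o in offs) word <- word * 2 + x[n + o]
  for (o in offs) word <- word * 2 + y[n - delta + o]
  structure(list(word = as.integer(word), x_s = x[n], y_s = y[n - delta],
                 n = n, delta = delta, omega = omega, bits = bits,
                 past_only = past_only),
            class = "conditioning_words")
}

#' @export
print.conditioning_words <- function(x, ...) {
  cat(sprintf("<conditioning_words> %d samples, delta %d, omega %d, %d-bit words%s\n",
              length(x$word), x$delta, x$omega, x$bits,
              if (x$past_only) " (past only)" else ""))
  invisible(x)
}

# The same windows as an explicit regressor matrix (columns in bit order),
# for the linear comparators.
window_matrix <- function(x, y, delta, omega, past_only = FALSE) {
  x <- as_binary_vector(x, "x")
  y <- as_binary_vector(y, "y")
  stopifnot(length(x) == length(y))
  delta <- as.integer(round(delta)); omega <- as.integer(round(omega))
  n <- valid_sample_range(length(x), delta, omega)
  if (length(n) == 0L) stop("trains too short: no sample has complete windows", call. = FALSE)
  offs <- window_offsets(omega, past_only)
  w <- if (omega >= 1) {
    cbind(vapply(offs, function(o) as.numeric(x[n + o]), numeric(length(n))),
          vapply(offs, function(o) as.numeric(y[n - delta + o]), numeric(length(n))))
  } else {
    matrix(numeric(0), nrow = length(n), ncol = 0)
  }
  list(n = n, x_s = as.numeric(x[n]), y_s = as.numeric(y[n - delta]), w = w)
}
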