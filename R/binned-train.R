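#' Bin spike times into a binary train
#'
#' Discretizes a list of spike times into time bins and returns the per-bin
#' spike indicator. Bins are half-open intervals
#' `[t_start + k * bin_width, t_start + (k + 1) * bin_width)`, indexed from
#' zero. The downstream information-theoretic measures assume at most one
#' spike per bin, so the bin width must be small enough that no bin receives
#' two spikes; a violation is an error, not a silent clip.
#'
#' @param spike_times numeric vector of spike times in seconds (any order).
#' @param bin_width bin width in seconds, > 0.
#' @param t_start start of the analysis window (seconds). Default 0.
#' @param t_end end of the analysis window (seconds, exclusive). Defaults to
#'   just past the last spike.
#' @return A `binned_train`: an integer vector of 0/1 values with
#'   `bin_width` and `t_start` attributes.
#' @examples
#' bin_spike_times(c(0.001, 0.005), 0.002, t_start = 0, t_end = 0.008)
#' @export
bin_spike_times <- function(spike_times, bin_width, t_start = 0, t_end = NULL) {
  stopifnot(is.numeric(spike_times), is.numeric(bin_width), length(bin_width) == 1L,
            bin_width > 0, is.numeric(t_start), length(t_start) == 1L)
  if (is.null(t_end)) {
    t_end <- if (length(spike_times)) max(spike_times) + bin_width else t_start + bin_width
  }
  if (t_end <= t_start) stop("`t_end` must be greater than `t_start`", call. = FALSE)
  n_bins <- floor((t_end - t_start) / bin_width + 1e-9)
  if (n_bins < 1L) stop("window shorter than one bin", call. = FALSE)
  st <- sort(spike_times)
  st <- st[st >= t_start & st < t_start + n_bins * bin_width]
  k <- floor((st - t_start) / bin_width)
  counts <- tabulate(as.integer(k) + 1L, n_bins)
  if (any(counts > 1L)) {
    bad <- which(counts > 1L)[1L] - 1L
    stop(sprintf(paste0(
      "bin %d ([%g, %g) s) holds %d spikes; the measures require binary bins. ",
      "Use a smaller `bin_width`."),
      bad, t_start + bad * bin_width, t_start + (bad + 1) * bin_width,
      counts[bad + 1L]), call. = FALSE)
  }
  new_binned_train(counts, bin_width = bin_width, t_start = t_start)
}

new_binned_train <- function(values, bin_width = NULL, t_start = NULL) {
  structure(as.integer(values), bin_width = bin_width, t_start = t_start,
            class = "binned_train")
}

#' Coerce a 0/1 vector to a binned train
#'
#' @param x integer/numeric/logical vector of 0s and 1s.
#' @param bin_width optional bin width in seconds (metadata only).
#' @return A `binned_train` object.
#' @export
as_binned_train <- function(x, bin_width = NULL) {
  if (inherits(x, "binned_train")) return(x)
  new_binned_train(as_binary_vector(x), bin_width = bin_width)
}

#' @export
print.binned_train <- function(x, ...) {
  bw <- attr(x, "bin_width")
  cat(sprintf("<binned_train> %d bins, %d spikes%s\n", length(x), sum(x),
              if (!is.null(bw)) sprintf(", bin width %g s", bw) else ""))
  invisible(x)
}

# Spike times recovered as bin centers of the nonzero bins; inverse of
# bin_spike_times up to within-bin position.
#' Bin centers of the spiking bins of a binned train
#'
#' @param x a `binned_train` with a `bin_width` attribute.
#' @return numeric vector of bin-center times (seconds).
#' @export
spike_bin_centers <- function(x) {
  stopifnot(inherits(x, "binned_train"))
  bw <- attr(x, "bin_width")
  t0 <- attr(x, "t_start") %||% 0
  if (is.null(bw)) stop("train carries no `bin_width` metadata", call. = FALSE)
  t0 + (which(unclass(x) == 1L) - 1L) * bw + bw / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
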