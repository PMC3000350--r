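# Delay profiles: a measure evaluated over a grid of integer delays,
# represented as a tibble subclass so results pipe into dplyr/ggplot2.

new_delay_profile <- function(df, measure, units = "dimensionless",
                              omega = NA_integer_, bias_corrected = NA) {
  stopifnot(all(c("delta", "value") %in% names(df)))
  if (is.unsorted(df$delta, strictly = TRUE)) {
    df <- df[order(df$delta), , drop = FALSE]
  }
  out <- tibble::as_tibble(df)
  attr(out, "measure") <- measure
  attr(out, "units") <- units
  attr(out, "omega") <- omega
  attr(out, "bias_corrected") <- bias_corrected
  class(out) <- c("delay_profile", class(out))
  out
}

#' @export
print.delay_profile <- function(x, ...) {
  cat(sprintf("# Delay profile: %s (%s)%s%s\n",
              attr(x, "measure") %||% "?", attr(x, "units") %||% "?",
              if (!is.na(attr(x, "omega") %||% NA)) sprintf(", omega = %d", attr(x, "omega")) else "",
              if (isTRUE(attr(x, "bias_corrected"))) ", bias-corrected" else ""))
  NextMethod()
}

#' Tidy a delay profile
#'
#' Returns the profile as a plain tibble (one row per delay), dropping the
#' `delay_profile` class and carrying the measure name as a column.
#'
#' @param x a `delay_profile`.
#' @param ... unused.
#' @return A tibble with columns `measure`, `delta`, `value` and any
#'   inference columns present.
#' @export
tidy.delay_profile <- function(x, ...) {
  out <- tibble::as_tibble(unclass_profile(x))
  tibble::add_column(out, measure = attr(x, "measure") %||% NA_character_,
                     .before = 1L)
}

#' One-row summary of a delay profile
#'
#' @param x a `delay_profile`.
#' @param ... unused.
#' @return A one-row tibble: measure, the delay of the maximum, the maximum
#'   value, the number of delays, window half-length and bias flag.
#' @export
glance.delay_profile <- function(x, ...) {
  i <- which.max(x$value)
  tibble::tibble(measure = attr(x, "measure") %||% NA_character_,
                 peak_delta = x$delta[i], peak_value = x$value[i],
                 n_deltas = nrow(x),
                 omega = attr(x, "omega") %||% NA_integer_,
                 bias_corrected = attr(x, "bias_corrected") %||% NA)
}

unclass_profile <- function(x) {
  class(x) <- setdiff(class(x), "delay_profile")
  for (a in c("measure", "units", "omega", "bias_corrected")) attr(x, a) <- NULL
  x
}

#' Plot a delay profile
#'
#' Line plot of the measure against delay, with the bootstrap confidence
#' band (ribbon) and the significance threshold (dashed line) when present.
#'
#' @param object a `delay_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.delay_profile <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$value))
  if (all(c("ci_low", "ci_high") %in% names(df)) && any(!is.na(df$ci_low))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                                  fill = "gold", alpha = 0.5)
  }
  p <- p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8)
  if ("sig_threshold" %in% names(df) && any(!is.na(df$sig_threshold))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$sig_threshold),
                                linetype = "dashed", colour = "red")
  }
  p + ggplot2::labs(x = "delay (bins)",
                    y = sprintf("%s (%s)", attr(object, "measure"), attr(object, "units")),
                    title = attr(object, "measure"))
}

#' @export
plot.delay_profile <- function(x, ...) print(autoplot(x, ...))

#' Plot several delay profiles side by side
#'
#' @param ... named `delay_profile` objects (names label the panels; unnamed
#'   profiles fall back to their measure name).
#' @return A ggplot object faceted by profile.
#' @export
plot_delay_profiles <- function(...) {
  profiles <- list(...)
  labels <- names(profiles) %||% rep("", length(profiles))
  if (is.null(names(profiles))) names(profiles) <- rep("", length(profiles))
  dfs <- lapply(seq_along(profiles), function(i) {
    d <- tidy(profiles[[i]])
    lab <- names(profiles)[i]
    if (!is.null(lab) && nzchar(lab)) d$measure <- lab
    d
  })
  df <- dplyr::bind_rows(dfs)
  df$measure <- factor(df$measure, levels = unique(df$measure))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "delay (bins)", y = "value")
}
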