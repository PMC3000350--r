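# Plain-text input/output: spike-time lists, binned 0/1 matrices, delay
# profiles, and YAML run-metadata sidecars.

#' Read a spike-time list
#'
#' Two-column delimited text: neuron id and spike time in seconds. A header
#' line is detected automatically (first line not parseable as two numbers).
#'
#' @param path file path.
#' @param sep field separator (default: any whitespace).
#' @return A tibble with columns `neuron_id`, `time`.
#' @export
read_spike_times <- function(path, sep = "") {
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), if (sep == "") "[[:space:],;\t]+" else sep)[[1L]]
  header <- length(fields) >= 2L && any(is.na(suppressWarnings(as.numeric(fields[1:2]))))
  df <- if (header) {
    utils::read.table(path, header = TRUE, sep = sep)
  } else {
    utils::read.table(path, header = FALSE, sep = sep,
                      col.names = c("neuron_id", "time"))
  }
  names(df)[1:2] <- c("neuron_id", "time")
  tibble::as_tibble(df[, 1:2])
}

#' Read / write binned 0/1 spike matrices
#'
#' Delimited text, one row per neuron (or per trial), one column per time
#' bin, values 0/1.
#'
#' @param path file path.
#' @return `read_binned()`: an integer matrix.
#' @export
read_binned <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    bad <- which(is.na(m) | !(m %in% c(0L, 1L)), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-binary value at row %d, column %d", path, bad[1L], bad[2L]),
         call. = FALSE)
  }
  m
}

#' @param x a 0/1 vector or matrix (rows = neurons or trials).
#' @rdname read_binned
#' @export
write_binned <- function(x, path) {
  m <- if (is.matrix(x)) x else matrix(as.integer(unclass(x)), nrow = 1L)
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

profile_columns <- c("delta", "value", "ci_low", "ci_high", "sig_threshold")

#' Read / write delay profiles as delimited text
#'
#' Tab-separated with a header; columns `delta`, `value`, `ci_low`,
#' `ci_high`, `sig_threshold` (missing inference columns written as NA).
#'
#' @param profile a `delay_profile`.
#' @param path file path.
#' @return `write_delay_profile()` returns `path` invisibly;
#'   `read_delay_profile()` returns a `delay_profile`.
#' @export
write_delay_profile <- function(profile, path) {
  df <- as.data.frame(unclass_profile(profile))
  for (cn in profile_columns) if (!cn %in% names(df)) df[[cn]] <- NA_real_
  utils::write.table(df[, profile_columns], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param measure measure label to attach on read (default `"profile"`).
#' @rdname write_delay_profile
#' @export
read_delay_profile <- function(path, measure = "profile") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  keep <- vapply(df, function(col) !all(is.na(col)), logical(1)) |
    names(df) %in% c("delta", "value")
  new_delay_profile(tibble::as_tibble(df[, keep, drop = FALSE]), measure = measure)
}

#' Write a run-metadata sidecar
#'
#' YAML file recording everything needed to regenerate an output: parameter
#' values, seed, and the package version.
#'
#' @param path file path (conventionally `<output>.meta.yaml`).
#' @param ... named parameter values to record.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, ...) {
  meta <- list(...)
  meta$package <- "incmi"
  meta$version <- as.character(utils::packageVersion("incmi"))
  yaml::write_yaml(meta, path)
  invisible(path)
}
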