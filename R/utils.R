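# Internal helpers shared across the package.

vemp_error <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "vemp_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

abort_argument <- function(msg) vemp_error("vemp_argument_error", msg)
abort_config <- function(msg) vemp_error("vemp_config_error", msg)
abort_insufficient <- function(msg) vemp_error("vemp_insufficient_data_error", msg)
abort_protocol <- function(msg) vemp_error("vemp_protocol_error", msg)
abort_schema <- function(msg) vemp_error("vemp_schema_error", msg)

#' Root-mean-square of a numeric vector
#'
#' @param x numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) sqrt(mean(x^2))

# Sample indices of the final `window_ms` before stimulus onset.
# `onset_index` is the 1-based index of the first post-onset sample, so the
# pre-stimulus window is the half-open interval [onset - window, onset).
prestim_indices <- function(onset_index, sample_rate, window_ms = 18) {
  n <- round(window_ms * sample_rate / 1000)
  if (onset_index - n < 1) {
    abort_argument(sprintf(
      "pre-stimulus span of %g ms needs %d samples before onset; only %d available",
      window_ms, n, onset_index - 1
    ))
  }
  seq.int(onset_index - n, onset_index - 1L)
}

# set.seed only when a seed is supplied; otherwise continue the current stream
with_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
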