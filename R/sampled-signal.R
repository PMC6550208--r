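#' Uniformly sampled signal
#'
#' Lightweight container for one channel of a recording: a numeric vector, its
#' sampling rate, and a unit label. All pipeline operations consume and return
#' `sampled_signal` objects so that sampling-rate bookkeeping cannot silently
#' go wrong.
#'
#' @param values Numeric vector of samples (finite, length >= 2).
#' @param fs Sampling rate in samples/s (> 0).
#' @param units Unit label, e.g. `"V"`, `"ohm"`, `"L/s"`, `"L"`.
#' @return An object of class `sampled_signal`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 0.25 * seq(0, 10, by = 0.01)), fs = 100, units = "V")
#' s
#' @export
sampled_signal <- function(values, fs, units = "") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a sampled_signal needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("signal values must be finite")
  structure(list(values = values, fs = fs, units = units),
            class = "sampled_signal")
}

as_sampled_signal <- function(x, fs = NULL, units = "") {
  if (inherits(x, "sampled_signal")) return(x)
  if (is.null(fs)) stop("`fs` required to build a sampled_signal from a vector")
  sampled_signal(x, fs, units)
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$values), x$fs, length(x$values) / x$fs,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Time axis of a sampled signal
#'
#' @param x A `sampled_signal`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  (seq_along(x$values) - 1) / x$fs
}

# Replace values, keeping fs; optionally relabel units.
reclothe <- function(x, values, units = NULL) {
  sampled_signal(values, x$fs, units %||% x$units)
}
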