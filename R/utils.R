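# Internal numerical helpers shared across the pipeline.

# Run code under a given RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Cumulative trapezoidal integral with first element 0.
cumtrapz1 <- function(t, y) {
  as.numeric(pracma::cumtrapz(t, y))
}

trapz1 <- function(t, y) {
  pracma::trapz(t, y)
}

#' One-sided amplitude spectrum of a real signal
#'
#' Returns frequencies (Hz) and amplitudes for the positive half of the DFT.
#' Frequency resolution is `fs / length(x)`.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in samples/s.
#' @param demean Subtract the mean before transforming (drops the DC bin's
#'   dependence on baseline level). Default `TRUE`.
#' @return A list with numeric vectors `freq_hz` and `amplitude`.
#' @keywords internal
#' @noRd
amplitude_spectrum <- function(x, fs, demean = TRUE) {
  if (demean) x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x)) / n
  half <- seq_len(floor(n / 2))
  list(freq_hz = (half - 1) * fs / n, amplitude = sp[half])
}

# Dominant frequency of x in (lo, hi] Hz; returns NA_real_ if no bins in band.
dominant_frequency <- function(x, fs, lo = 0, hi = fs / 2) {
  sp <- amplitude_spectrum(x, fs)
  keep <- sp$freq_hz > lo & sp$freq_hz <= hi
  if (!any(keep)) return(NA_real_)
  sp$freq_hz[keep][which.max(sp$amplitude[keep])]
}

#' Local maxima filtered by topographic prominence
#'
#' A sample is a candidate peak if the signal rises into it and falls after it
#' (the last sample of a flat top is taken for ties). Prominence of a peak is
#' its height above the higher of the two minima separating it from the nearest
#' higher ground on each side, the usual topographic definition.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence a peak must have to be kept.
#' @return Integer vector of peak indices (possibly empty), in order.
#' @keywords internal
#' @noRd
find_peaks <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # rising-then-falling, tolerating flat tops: take last sample of a plateau
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo::na.locf(s, na.rm = FALSE)
  s <- zoo::na.locf(s, fromLast = TRUE)
  if (anyNA(s)) return(integer(0))  # flat signal
  cand <- which(diff(s) < 0) + 1
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- if (i > 1) x[seq_len(i - 1)] else numeric(0)
    right <- if (i < n) x[seq(i + 1, n)] else numeric(0)
    hi_l <- which(left > h)
    base_l <- if (length(hi_l)) min(left[seq(max(hi_l), length(left))]) else min(c(left, h))
    hi_r <- which(right > h)
    base_r <- if (length(hi_r)) min(right[seq_len(min(hi_r))]) else min(c(right, h))
    h - max(base_l, base_r)
  }, numeric(1))
  cand[prom >= min_prominence]
}

# Short deterministic hash of an R object, for provenance stamps in outputs.
config_hash <- function(x) {
  digest::digest(x, algo = "xxhash64")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
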