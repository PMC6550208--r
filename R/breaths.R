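#' Segment breaths from a flow signal
#'
#' Splits the flow trace at its zero-crossings into signed lobes (positive
#' flow = exhalation), discards lobes whose absolute volume is below the
#' noise cutoff (0.01 L by convention) — merging same-signed lobes that
#' become adjacent after a discard — and pairs each inhalation lobe with the
#' following exhalation lobe into one breath. Volumes are trapezoidal
#' integrals of the signed lobes; the peak-to-peak period is the spacing of
#' successive exhalation flow peaks.
#'
#' @param flow A `sampled_signal` in L/s.
#' @param min_volume_l Noise cutoff volume, L.
#' @return A data frame of class `breath_table`: `breath_id`, `start_idx`,
#'   `end_idx` (1-based, inclusive), `start_s`, `end_s`, `exhaled_l`,
#'   `inhaled_l`, `period_s` (NA for the last breath). Empty (0 rows) when
#'   the flow never completes a breath.
#' @examples
#' fs <- 200
#' t <- seq(0, 8 - 1 / fs, by = 1 / fs)
#' fl <- sampled_signal(sin(2 * pi * t / 4), fs, "L/s")
#' segment_breaths(fl)   # two breaths of 4/pi L each
#' @export
segment_breaths <- function(flow, min_volume_l = 0.01) {
  stopifnot(inherits(flow, "sampled_signal"))
  x <- flow$values
  fs <- flow$fs
  tt <- signal_time(flow)
  s <- sign(x)
  if (all(s >= 0) || all(s <= 0)) return(empty_breath_table())
  # zero samples belong to the preceding lobe
  s[s == 0] <- NA
  s <- zoo::na.locf(s, na.rm = FALSE)
  s <- zoo::na.locf(s, fromLast = TRUE)  # leading zeros join the first lobe
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lobes <- data.frame(start = starts, end = ends, sgn = r$values)
  lobes$vol <- vapply(seq_len(nrow(lobes)), function(i) {
    w <- lobes$start[i]:lobes$end[i]
    trapz1(tt[w], x[w])
  }, numeric(1))
  # drop sub-cutoff noise lobes, then merge same-signed neighbours
  lobes <- lobes[abs(lobes$vol) >= min_volume_l, , drop = FALSE]
  if (nrow(lobes) == 0) return(empty_breath_table())
  merged <- lobes[1, , drop = FALSE]
  for (i in seq_len(nrow(lobes))[-1]) {
    last <- nrow(merged)
    if (lobes$sgn[i] == merged$sgn[last]) {
      merged$end[last] <- lobes$end[i]
      merged$vol[last] <- merged$vol[last] + lobes$vol[i]
    } else {
      merged <- rbind(merged, lobes[i, ])
    }
  }
  # pair inhale (negative) lobe with the following exhale (positive) lobe
  rows <- list()
  i <- 1L
  while (i < nrow(merged)) {
    if (merged$sgn[i] < 0 && merged$sgn[i + 1] > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        start_idx = merged$start[i], end_idx = merged$end[i + 1],
        exhaled_l = merged$vol[i + 1], inhaled_l = -merged$vol[i])
      i <- i + 2L
    } else i <- i + 1L
  }
  if (!length(rows)) return(empty_breath_table())
  br <- do.call(rbind, rows)
  br <- data.frame(breath_id = seq_len(nrow(br)), br)
  br$start_s <- (br$start_idx - 1) / fs
  br$end_s <- (br$end_idx - 1) / fs
  # peak-to-peak period from exhalation flow maxima
  pk <- vapply(seq_len(nrow(br)), function(k) {
    w <- br$start_idx[k]:br$end_idx[k]
    tt[w[which.max(x[w])]]
  }, numeric(1))
  br$period_s <- c(diff(pk), NA_real_)
  class(br) <- c("breath_table", "data.frame")
  br
}

empty_breath_table <- function() {
  out <- data.frame(breath_id = integer(0), start_idx = integer(0),
                    end_idx = integer(0), exhaled_l = numeric(0),
                    inhaled_l = numeric(0), start_s = numeric(0),
                    end_s = numeric(0), period_s = numeric(0))
  class(out) <- c("breath_table", "data.frame")
  out
}

#' Per-breath resistance excursion
#'
#' The raw predictor of breath volume: `max(r) - min(r)` within the breath
#' window, extended by a guard interval on each side to absorb the phase lag
#' between airflow and skin strain.
#'
#' @param r Strain `sampled_signal` in ohm.
#' @param start_idx,end_idx Breath window, 1-based inclusive sample indices.
#' @param guard_s Guard extension each side, s.
#' @return Resistance excursion in ohm (>= 0).
#' @export
breath_delta_r <- function(r, start_idx, end_idx, guard_s = 0.25) {
  stopifnot(inherits(r, "sampled_signal"), start_idx < end_idx)
  g <- round(guard_s * r$fs)
  w <- max(1L, start_idx - g):min(length(r$values), end_idx + g)
  max(r$values[w]) - min(r$values[w])
}

#' Annotate a breath table with per-sensor resistance excursions
#'
#' @param breaths A `breath_table` from [segment_breaths()].
#' @param rib,abd Strain `sampled_signal`s in ohm.
#' @param guard_s Guard extension passed to [breath_delta_r()].
#' @return The breath table with added columns `dr_rib_ohm`, `dr_abd_ohm`.
#' @export
add_delta_r <- function(breaths, rib, abd, guard_s = 0.25) {
  breaths$dr_rib_ohm <- vapply(seq_len(nrow(breaths)), function(k)
    breath_delta_r(rib, breaths$start_idx[k], breaths$end_idx[k], guard_s),
    numeric(1))
  breaths$dr_abd_ohm <- vapply(seq_len(nrow(breaths)), function(k)
    breath_delta_r(abd, breaths$start_idx[k], breaths$end_idx[k], guard_s),
    numeric(1))
  breaths
}

#' Peak-to-peak periods of a quasi-periodic signal
#'
#' Detects peaks by topographic prominence and returns the successive
#' differences of their times; the mean of the result estimates the breath
#' period. The default prominence threshold adapts to the signal: a quarter
#' of its interquartile range.
#'
#' @param x A `sampled_signal`.
#' @param min_prominence Minimum peak prominence, in signal units. Default
#'   `0.25 * IQR(x)`.
#' @return Numeric vector of periods in seconds (possibly empty).
#' @export
peak_periods <- function(x, min_prominence = NULL) {
  stopifnot(inherits(x, "sampled_signal"))
  if (is.null(min_prominence))
    min_prominence <- 0.25 * stats::IQR(x$values)
  if (min_prominence <= 0) return(numeric(0))
  pk <- find_peaks(x$values, min_prominence)
  if (length(pk) < 2) return(numeric(0))
  diff((pk - 1) / x$fs)
}
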