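#' Predict per-breath volume from resistance excursions
#'
#' Convenience wrapper around [predict.kono_mead()] for explicit vectors.
#'
#' @param model A `kono_mead` model.
#' @param delta_r_rib,delta_r_abd Resistance excursions, ohm
#'   (`delta_r_abd` ignored for single-compartment models).
#' @return Predicted volumes in L, floored at 0.
#' @export
predict_volume <- function(model, delta_r_rib, delta_r_abd = NULL) {
  nd <- data.frame(dr_rib = delta_r_rib)
  if (!is.null(delta_r_abd)) nd$dr_abd <- delta_r_abd
  predict(model, nd)
}

#' Respiration rate from peak-to-peak periods
#'
#' `60 / mean(peak_periods(x))`: the time-domain rate estimate used for
#' metronome-paced breathing.
#'
#' @param x A `sampled_signal` (detrended strain or volume channel).
#' @param min_prominence Passed to [peak_periods()].
#' @return Rate in breaths/min (NA if fewer than two peaks are found).
#' @export
estimate_rate_periods <- function(x, min_prominence = NULL) {
  p <- peak_periods(x, min_prominence)
  if (!length(p)) return(NA_real_)
  60 / mean(p)
}

#' Respiration rate from the frequency domain
#'
#' Dominant spectral peak of the (demeaned) signal within the respiration
#' band. Frequency resolution is the FFT bin width, `fs / length(x)`.
#'
#' @param x A `sampled_signal`.
#' @param band_hz Two-element `(lo, hi)` band in Hz; default 0.05-1.2 Hz
#'   (3-72 breaths/min).
#' @return Dominant frequency in Hz.
#' @export
estimate_rate_fft <- function(x, band_hz = c(0.05, 1.2)) {
  stopifnot(inherits(x, "sampled_signal"))
  if (length(band_hz) != 2 || band_hz[1] >= band_hz[2])
    stop("band_hz must be (lo, hi) with lo < hi")
  f <- dominant_frequency(x$values, x$fs, band_hz[1], band_hz[2])
  if (is.na(f)) stop("no FFT bins inside the requested band")
  f
}

#' Spirometry metrics from an exhaled-volume trace
#'
#' FEV1 is the volume exhaled 1 s after the exhale start; FVC is the volume
#' at the end of the required 6 s sustain (plateau); FEV1% is
#' `100 * FEV1 / FVC`.
#'
#' @param volume_trace A `sampled_signal` in L: cumulative exhaled volume
#'   (nondecreasing during the maneuver).
#' @param exhale_start_idx 1-based sample index of the exhale start.
#' @return A list of class `spirometry_metrics` with `fev1`, `fvc`,
#'   `fev1_pct`.
#' @examples
#' fs <- 100
#' t <- seq(0, 8, by = 1 / fs)
#' v <- sampled_signal(4 * (1 - exp(-t / 0.5)), fs, "L")
#' compute_spirometry(v, 1)
#' @export
compute_spirometry <- function(volume_trace, exhale_start_idx) {
  stopifnot(inherits(volume_trace, "sampled_signal"))
  fs <- volume_trace$fs
  v <- volume_trace$values
  i0 <- exhale_start_idx
  if (i0 < 1 || i0 + round(6 * fs) > length(v))
    stop("volume trace must cover at least 6 s after the exhale start")
  v0 <- v[i0]
  fev1 <- v[i0 + round(1 * fs)] - v0
  fvc <- v[i0 + round(6 * fs)] - v0
  out <- list(fev1 = fev1, fvc = fvc,
              fev1_pct = if (fvc > 0) 100 * fev1 / fvc else NA_real_)
  class(out) <- "spirometry_metrics"
  out
}

#' @export
print.spirometry_metrics <- function(x, ...) {
  cat(sprintf("FEV1 = %.3f L, FVC = %.3f L, FEV1%% = %.1f\n",
              x$fev1, x$fvc, x$fev1_pct))
  invisible(x)
}

#' Locate the start of a forced exhalation
#'
#' The last sample at or below the flow threshold before the first sustained
#' (>= 0.2 s) run of positive flow above the threshold.
#'
#' @param flow A `sampled_signal` in L/s (positive = exhalation).
#' @param threshold_l_s Flow threshold, L/s.
#' @return 1-based sample index.
#' @export
find_exhale_start <- function(flow, threshold_l_s = 0.1) {
  stopifnot(inherits(flow, "sampled_signal"))
  x <- flow$values
  fs <- flow$fs
  above <- x > threshold_l_s
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  sustained <- which(r$values & r$lengths >= round(0.2 * fs))
  if (!length(sustained)) stop("no sustained exhalation found")
  max(starts[sustained[1]] - 1L, 1L)
}

#' Score forced maneuvers and select the best three
#'
#' Applies [compute_spirometry()] to each maneuver and ranks by FVC + FEV1
#' (the acceptability-and-best-test convention); given five maneuvers the top
#' three are flagged as selected.
#'
#' @param traces List of `sampled_signal` exhaled-volume traces, one per
#'   maneuver.
#' @param exhale_start_idx Vector of exhale-start indices (recycled if
#'   length 1).
#' @param n_select Number of maneuvers to select (default 3).
#' @return Data frame: `maneuver_id`, `fev1_l`, `fvc_l`, `fev1_pct`,
#'   `selected`.
#' @export
rank_maneuvers <- function(traces, exhale_start_idx = 1L, n_select = 3) {
  k <- length(traces)
  i0 <- rep_len(exhale_start_idx, k)
  res <- lapply(seq_len(k), function(j) compute_spirometry(traces[[j]], i0[j]))
  out <- data.frame(maneuver_id = seq_len(k),
                    fev1_l = vapply(res, `[[`, numeric(1), "fev1"),
                    fvc_l = vapply(res, `[[`, numeric(1), "fvc"),
                    fev1_pct = vapply(res, `[[`, numeric(1), "fev1_pct"))
  score <- out$fvc_l + out$fev1_l
  sel <- order(score, decreasing = TRUE)[seq_len(min(n_select, k))]
  out$selected <- seq_len(k) %in% sel
  out
}

#' Spirometry as seen by the strain sensors
#'
#' Converts the instantaneous strain excursions during a forced maneuver into
#' a calculated exhaled-volume trace: lung volume above the pre-maneuver
#' end-expiratory baseline is predicted from the per-sensor resistance
#' excursion at every sample through the calibration model, and the exhaled
#' volume is the drop from its value at the exhale start. Sensor hysteresis
#' (slow resistance return) makes this trace under-read the spirometer
#' during fast forced exhalations.
#'
#' @param model A `kono_mead` model.
#' @param rib,abd Strain `sampled_signal`s in ohm covering the maneuver.
#' @param exhale_start_idx 1-based index of the exhale start within the
#'   window.
#' @param baseline_window_s Seconds at the start of the window used as the
#'   end-expiratory resistance baseline.
#' @return A `sampled_signal` in L: calculated exhaled volume, 0 before the
#'   exhale start.
#' @export
strain_volume_trace <- function(model, rib, abd, exhale_start_idx,
                                baseline_window_s = 0.5) {
  stopifnot(inherits(model, "kono_mead"))
  fs <- rib$fs
  nb <- max(2L, round(baseline_window_s * fs))
  dr_rib <- pmax(rib$values - min(rib$values[seq_len(nb)]), 0)
  dr_abd <- pmax(abd$values - min(abd$values[seq_len(nb)]), 0)
  v_lung <- predict_volume(model, dr_rib, dr_abd)
  exhaled <- pmax(v_lung[exhale_start_idx] - v_lung, 0)
  exhaled[seq_len(exhale_start_idx - 1)] <- 0
  sampled_signal(exhaled, fs, "L")
}
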