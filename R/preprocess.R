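#' Remove isolated voltage spikes with a sliding-median detector
#'
#' Samples deviating from the running median by more than 6 times the robust
#' spread (median absolute deviation of the deviations) are replaced by the
#' running median. Smooth signals pass through unchanged.
#'
#' @param v A `sampled_signal` (typically the raw spirometer voltage).
#' @param window_s Window length in seconds; must cover at least 3 samples.
#' @param k Threshold in MADs. Default 6.
#' @return A `sampled_signal` of the same length and rate.
#' @export
despike <- function(v, window_s = 0.05, k = 6) {
  stopifnot(inherits(v, "sampled_signal"))
  w <- round(window_s * v$fs)
  if (w < 3) stop("despike window must cover at least 3 samples")
  if (w %% 2 == 0) w <- w + 1
  x <- v$values
  med <- stats::runmed(x, w, endrule = "median")
  dev <- x - med
  s <- stats::mad(dev)
  if (s == 0) s <- stats::sd(dev)
  if (is.na(s) || s == 0) return(v)  # perfectly smooth: nothing to do
  out <- ifelse(abs(dev) > k * s, med, x)
  reclothe(v, out)
}

#' Convert spirometer voltage to airflow
#'
#' Pointwise scaling by the spirometer's calibration constant
#' (2.04 L/(s V) for the acquisition chain this pipeline targets).
#'
#' @param v A `sampled_signal` in V.
#' @param constant Conversion constant in L/(s V).
#' @return A `sampled_signal` in L/s.
#' @export
voltage_to_flow <- function(v, constant = 2.04) {
  stopifnot(inherits(v, "sampled_signal"))
  reclothe(v, v$values * constant, units = "L/s")
}

#' Integrate airflow to volume
#'
#' Cumulative trapezoidal integral of the flow; the first sample is 0. With
#' positive flow meaning exhalation, the result decreases during inhalation.
#'
#' @param q A `sampled_signal` in L/s.
#' @return A `sampled_signal` in L.
#' @export
integrate_flow <- function(q) {
  stopifnot(inherits(q, "sampled_signal"))
  reclothe(q, cumtrapz1(signal_time(q), q$values), units = "L")
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so breath timing is not shifted and passband components (below half the
#' cutoff) are attenuated by less than 1%.
#'
#' @param x A `sampled_signal`.
#' @param cutoff_hz Cutoff frequency in Hz; must satisfy
#'   `0 < cutoff_hz < fs/2`.
#' @param order Filter order (applied twice by the forward-backward pass).
#' @return A filtered `sampled_signal`.
#' @export
lowpass <- function(x, cutoff_hz = 20, order = 4) {
  stopifnot(inherits(x, "sampled_signal"))
  nyq <- x$fs / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq))
    stop("cutoff_hz must lie in (0, fs/2)")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  y <- x$values
  n <- length(y)
  mu <- mean(y)
  y <- y - mu
  # odd-reflection padding so the zero-state filter start-up transient decays
  # inside the discarded pad rather than in the signal
  pad <- min(n - 1L, ceiling(3 * x$fs / cutoff_hz))
  left <- 2 * y[1] - y[(pad + 1):2]
  right <- 2 * y[n] - y[(n - 1):(n - pad)]
  z <- signal::filtfilt(bf, c(left, y, right))
  reclothe(x, z[(pad + 1):(pad + n)] + mu)
}

#' Correct baseline jumps left by sensor hysteresis
#'
#' Large, abrupt stretches leave the piezo-resistive sensor with a shifted
#' end-expiratory baseline that relaxes only slowly. This pass estimates the
#' end-expiratory baseline as a running minimum over about 1.5 breath
#' periods, detects step changes in that baseline larger than
#' `jump_threshold`, locates each step's true position from the raw signal's
#' largest local increment, and subtracts the cumulative steps so the
#' baseline is piecewise-continuous while within-breath morphology is
#' untouched.
#'
#' @param r A `sampled_signal` in ohm.
#' @param jump_threshold Minimum baseline step to remove, ohm.
#' @param window_s Running-minimum window, s (about 1.5 breath periods).
#' @return A corrected `sampled_signal` in ohm.
#' @export
correct_hysteresis <- function(r, jump_threshold = 1, window_s = 6) {
  stopifnot(inherits(r, "sampled_signal"))
  x <- r$values
  n <- length(x)
  fs <- r$fs
  # decimate for the rolling minimum; baseline is slow by construction
  step <- max(1L, floor(fs / 50))
  idx <- seq(1L, n, by = step)
  w <- max(3L, round(window_s * fs / step / 2) * 2 + 1)
  bl <- as.numeric(zoo::rollapply(zoo::zoo(x[idx]), w, min,
                                  partial = TRUE, align = "center"))
  db <- diff(bl)
  jumps <- which(abs(db) > jump_threshold)
  if (!length(jumps)) return(r)
  # collapse runs of adjacent detections into single steps
  grp <- cumsum(c(1, diff(jumps) > 1))
  correction <- numeric(n)
  for (g in unique(grp)) {
    jj <- jumps[grp == g]
    size <- sum(db[jj])
    # locate the true step near the baseline jump via the raw increment
    centre <- idx[max(jj)]
    lo <- max(2L, centre - w * step)
    hi <- min(n, centre + w * step)
    k <- lo + which.max(abs(diff(x[(lo - 1):hi]))) - 1L
    correction[k:n] <- correction[k:n] + size
  }
  reclothe(r, x - correction)
}

#' Accelerometer-guided motion-artifact filter
#'
#' Low-pass filters a strain channel with a cutoff derived from the dominant
#' (non-DC) spectral peak of an accelerometer channel — the step cadence —
#' under the assumption that respiration is slower than locomotion. The
#' cutoff is `cut_factor` times the cadence, floored at `floor_hz` and capped
#' at `cadence - cap_margin_hz`.
#'
#' @param r Strain `sampled_signal` in ohm.
#' @param accel Accelerometer `sampled_signal` in V.
#' @param cut_factor,floor_hz,cap_margin_hz Cutoff rule constants.
#' @param min_peak_ratio Minimum ratio of the dominant peak amplitude to the
#'   median spectral amplitude for locomotion to count as detected.
#' @return List with `signal` (filtered `sampled_signal`), `cutoff_hz`, and
#'   `cadence_hz`.
#' @export
motion_filter <- function(r, accel, cut_factor = 0.5, floor_hz = 0.5,
                          cap_margin_hz = 0.2, min_peak_ratio = 10) {
  stopifnot(inherits(r, "sampled_signal"), inherits(accel, "sampled_signal"))
  sp <- amplitude_spectrum(accel$values, accel$fs)
  keep <- sp$freq_hz > 0.25  # exclude DC / gravity leakage
  amp <- sp$amplitude[keep]
  frq <- sp$freq_hz[keep]
  i <- which.max(amp)
  if (amp[i] < min_peak_ratio * stats::median(amp))
    stop("no locomotion detected: accelerometer has no dominant spectral peak")
  cadence <- frq[i]
  cutoff <- min(max(cut_factor * cadence, floor_hz), cadence - cap_margin_hz)
  list(signal = lowpass(r, cutoff), cutoff_hz = cutoff, cadence_hz = cadence)
}

#' Remove the best-fit line from a signal
#'
#' Ordinary least-squares detrending: the output has zero mean and zero
#' linear trend. Used before plotting and peak-based rate estimation.
#'
#' @param x A `sampled_signal`.
#' @return A detrended `sampled_signal`.
#' @export
detrend <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  t <- signal_time(x)
  y <- x$values
  tc <- t - mean(t)
  slope <- sum(tc * y) / sum(tc^2)
  reclothe(x, y - mean(y) - slope * tc)
}

#' Preprocess a recording into analysis-ready signals
#'
#' Standard chain: despike the spirometer voltage, scale to flow, integrate
#' to volume; low-pass the strain channels at 20 Hz, correct hysteresis
#' baseline jumps, and (when requested or when locomotion is present) apply
#' the accelerometer-guided motion filter.
#'
#' @param rec A `respiration_recording`.
#' @param despike_window_s Spike-filter window, s.
#' @param lowpass_cutoff_hz Strain low-pass cutoff, Hz.
#' @param jump_threshold Hysteresis-jump threshold, ohm.
#' @param motion `"auto"` (apply the motion filter if the accelerometer shows
#'   a dominant peak), `TRUE` (require it; error if no peak), or `FALSE`.
#' @param accel_channel Accelerometer column used for cadence detection.
#' @return List with `sampled_signal`s `flow` (L/s), `volume` (L), `rib`,
#'   `abd` (ohm), plus `motion_cutoff_hz` (NA if no motion filtering).
#' @export
preprocess_recording <- function(rec, despike_window_s = 0.05,
                                 lowpass_cutoff_hz = 20,
                                 jump_threshold = 1,
                                 motion = "auto",
                                 accel_channel = "ay_v") {
  stopifnot(inherits(rec, "respiration_recording"))
  spiro <- despike(recording_channel(rec, "spiro_v"), despike_window_s)
  flow <- voltage_to_flow(spiro, rec$flow_constant_l_per_sv)
  volume <- integrate_flow(flow)
  rib <- correct_hysteresis(lowpass(recording_channel(rec, "rib_ohm"),
                                    lowpass_cutoff_hz), jump_threshold)
  abd <- correct_hysteresis(lowpass(recording_channel(rec, "abd_ohm"),
                                    lowpass_cutoff_hz), jump_threshold)
  cutoff <- NA_real_
  if (!identical(motion, FALSE)) {
    accel <- recording_channel(rec, accel_channel)
    res <- tryCatch({
      mr <- motion_filter(rib, accel)
      ma <- motion_filter(abd, accel)
      list(rib = mr$signal, abd = ma$signal, cutoff = mr$cutoff_hz)
    }, error = function(e) {
      if (isTRUE(motion)) stop(e)
      NULL
    })
    if (!is.null(res)) {
      rib <- res$rib; abd <- res$abd; cutoff <- res$cutoff
    }
  }
  list(flow = flow, volume = volume, rib = rib, abd = abd,
       motion_cutoff_hz = cutoff)
}
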