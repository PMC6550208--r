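#' Configuration for the synthetic recording generator
#'
#' Builds the parameter set for [generate_recording()]. Defaults emulate the
#' study conditions of the reclined-subject protocol: 1000 Hz acquisition,
#' shallow/medium/deep calibration amplitudes of 0.5/1.0/2.0 L, resting tidal
#' volume 0.8 L at 15 breaths/min, a power-law resistance response
#' `R = baseline + a * v^b` per compartment with exponents 1.4 (ribcage) and
#' 1.2 (abdomen), Gaussian sensor noise, random-walk baseline drift, optional
#' viscoelastic hysteresis (slow return to baseline after large stretch), and
#' optional locomotion artifacts with a half-cadence component.
#'
#' @param schedule Data frame with columns `phase` (label), `duration_s`,
#'   `tidal_l` (target tidal volume in L; `NA` draws each breath at random from
#'   the shallow/medium/deep `amplitude_levels`, as in the free-order test
#'   protocol), and optionally `rate_bpm`. Defaults to [protocol_schedule()]
#'   for the calibration protocol.
#' @param duration_s Total recording length in seconds. Defaults to the
#'   schedule's total; must be at least that (the remainder is quiet).
#' @param fs Sampling rate, samples/s.
#' @param breath_rate_bpm Breathing rate used by phases without their own
#'   `rate_bpm` column.
#' @param amplitude_levels Named vector of tidal volumes (L) for the
#'   `shallow`, `medium`, `deep`, and `tidal` phase labels.
#' @param amplitude_cv Coefficient of variation of per-breath tidal-volume
#'   jitter (natural breath-to-breath variability). Set 0 for exact volumes.
#' @param rib_fraction Fraction of each breath's volume moving the ribcage
#'   compartment, in `[0, 1]`; the remainder moves the abdomen.
#' @param power_params_rib,power_params_abd Named vectors `c(a = , b = )` of
#'   the forward resistance response (ohm per L^b scale, dimensionless
#'   exponent; `b > 0`).
#' @param baseline_ohm Unstrained sensor resistance, ohm.
#' @param noise_sd_ohm SD of additive Gaussian resistance noise, ohm.
#' @param drift_rate_ohm_per_s Scale of random-walk baseline drift: SD of the
#'   walk after 1 s, ohm.
#' @param hysteresis_tau_s Relaxation time (s) of the slow return to baseline
#'   after a large stretch; 0 disables hysteresis.
#' @param hysteresis_frac Fraction of the recent excursion range beyond which
#'   a stretch engages the slow-return term.
#' @param motion `NULL` (no locomotion) or a list with `cadence_hz`,
#'   `strain_artifact_amp_ohm`, `half_cadence_amp_ohm`, `accel_amp_v`.
#' @param flow_constant_l_per_sv Spirometer conversion constant, L/(s V).
#' @param pft_depth_l,pft_inhale_s,pft_exhale_tau_s,pft_rest_s Forced-maneuver
#'   shape for the `pft` phase label: inspiratory capacity (L), inhale
#'   duration (s), exponential exhale time constant (s), rest between
#'   maneuvers (s).
#' @param seed Integer seed; identical configurations with identical seeds
#'   yield bit-identical recordings.
#' @return A list of class `generator_config`.
#' @seealso [generate_recording()], [protocol_schedule()]
#' @export
generator_config <- function(schedule = protocol_schedule("calibration"),
                             duration_s = NULL,
                             fs = 1000,
                             breath_rate_bpm = 15,
                             amplitude_levels = c(shallow = 0.5, medium = 1.0,
                                                  deep = 2.0, tidal = 0.8),
                             amplitude_cv = 0.05,
                             rib_fraction = 0.4,
                             power_params_rib = c(a = 2.0, b = 1.4),
                             power_params_abd = c(a = 2.0, b = 1.2),
                             baseline_ohm = 4700,
                             noise_sd_ohm = 0.03,
                             drift_rate_ohm_per_s = 0.01,
                             hysteresis_tau_s = 0,
                             hysteresis_frac = 0.5,
                             motion = NULL,
                             flow_constant_l_per_sv = 2.04,
                             pft_depth_l = 4.0,
                             pft_inhale_s = 2.0,
                             pft_exhale_tau_s = 0.5,
                             pft_rest_s = 45,
                             seed = 1L) {
  stopifnot(is.data.frame(schedule),
            all(c("phase", "duration_s", "tidal_l") %in% names(schedule)))
  cfg <- list(schedule = schedule, duration_s = duration_s, fs = fs,
              breath_rate_bpm = breath_rate_bpm,
              amplitude_levels = amplitude_levels,
              amplitude_cv = amplitude_cv,
              rib_fraction = rib_fraction,
              power_params_rib = power_params_rib,
              power_params_abd = power_params_abd,
              baseline_ohm = baseline_ohm,
              noise_sd_ohm = noise_sd_ohm,
              drift_rate_ohm_per_s = drift_rate_ohm_per_s,
              hysteresis_tau_s = hysteresis_tau_s,
              hysteresis_frac = hysteresis_frac,
              motion = motion,
              flow_constant_l_per_sv = flow_constant_l_per_sv,
              pft_depth_l = pft_depth_l,
              pft_inhale_s = pft_inhale_s,
              pft_exhale_tau_s = pft_exhale_tau_s,
              pft_rest_s = pft_rest_s,
              seed = as.integer(seed))
  cfg$schedule <- resolve_schedule(cfg)
  if (is.null(cfg$duration_s)) cfg$duration_s <- sum(cfg$schedule$duration_s)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$fs <= 0) stop("fs must be positive")
  if (cfg$duration_s <= 0) stop("duration_s must be positive")
  if (sum(cfg$schedule$duration_s) > cfg$duration_s + 1e-9)
    stop("schedule total duration (", sum(cfg$schedule$duration_s),
         " s) exceeds duration_s (", cfg$duration_s, " s)")
  if (cfg$rib_fraction < 0 || cfg$rib_fraction > 1)
    stop("rib_fraction must be in [0, 1]")
  if (any(cfg$amplitude_levels < 0) ||
      any(cfg$schedule$tidal_l < 0, na.rm = TRUE))
    stop("tidal amplitudes must be >= 0")
  for (p in list(cfg$power_params_rib, cfg$power_params_abd)) {
    if (!all(c("a", "b") %in% names(p)) || p[["b"]] <= 0)
      stop("power params need a and b with b > 0")
  }
  invisible(cfg)
}

#' Breathing schedules for the study protocols
#'
#' Phase tables mirroring the test-session structure: `calibration` (30 s
#' tidal, then 1 min each at shallow/medium/deep amplitude, then 30 s tidal),
#' `paced` (metronome-paced breathing at 10/20/40 breaths/min for
#' 2 min/1 min/30 s), `test` (3 min of shallow/medium/deep breaths in random
#' order, tidal bookends), `pft` (5 forced maneuvers with rests), and
#' `motion` (2 min paced at 20 breaths/min, for walking experiments).
#'
#' @param protocol One of `"calibration"`, `"paced"`, `"test"`, `"pft"`,
#'   `"motion"`.
#' @param rate_bpm Pacing rate for the `paced` protocol (10, 20, or 40
#'   breaths/min; other values allowed).
#' @param duration_s Paced-phase duration; defaults to the protocol duration
#'   for the chosen rate (120/60/30 s) or 60 s otherwise.
#' @return Data frame with columns `phase`, `duration_s`, `tidal_l`,
#'   `rate_bpm`.
#' @export
protocol_schedule <- function(protocol = c("calibration", "paced", "test",
                                           "pft", "motion"),
                              rate_bpm = 20, duration_s = NULL) {
  protocol <- match.arg(protocol)
  ph <- function(phase, dur, tidal, rate = NA_real_)
    data.frame(phase = phase, duration_s = dur, tidal_l = tidal,
               rate_bpm = rate, stringsAsFactors = FALSE)
  switch(protocol,
    calibration = rbind(ph("tidal", 30, NA_real_),
                        ph("shallow", 60, NA_real_),
                        ph("medium", 60, NA_real_),
                        ph("deep", 60, NA_real_),
                        ph("tidal", 30, NA_real_)),
    paced = {
      if (is.null(duration_s))
        duration_s <- c(`10` = 120, `20` = 60, `40` = 30)[as.character(rate_bpm)]
      if (is.na(duration_s)) duration_s <- 60
      ph("paced", duration_s, NA_real_, rate_bpm)
    },
    test = rbind(ph("tidal", 30, NA_real_),
                 ph("test", 180, NA_real_),
                 ph("tidal", 30, NA_real_)),
    pft = {
      rows <- list()
      for (k in 1:5) {
        rows[[length(rows) + 1L]] <- ph("pft", NA_real_, NA_real_)
        if (k < 5) rows[[length(rows) + 1L]] <- ph("rest", NA_real_, 0)
      }
      do.call(rbind, rows)
    },
    motion = ph("paced", 120, NA_real_, 20))
}

# Resolve NA tidal volumes / durations in a schedule against a config.
resolve_schedule <- function(cfg) {
  sched <- cfg$schedule
  if (!"rate_bpm" %in% names(sched)) sched$rate_bpm <- NA_real_
  lv <- cfg$amplitude_levels
  for (i in seq_len(nrow(sched))) {
    p <- sched$phase[i]
    if (p == "paced") p <- "tidal"  # paced breathing at resting tidal volume
    if (is.na(sched$tidal_l[i]) && p %in% names(lv))
      sched$tidal_l[i] <- lv[[p]]
    p <- sched$phase[i]
    if (p == "pft") {
      if (is.na(sched$tidal_l[i])) sched$tidal_l[i] <- cfg$pft_depth_l
      if (is.na(sched$duration_s[i]))
        sched$duration_s[i] <- cfg$pft_inhale_s + 7  # 1 s quiet tail
    }
    if (p == "rest" && is.na(sched$duration_s[i]))
      sched$duration_s[i] <- cfg$pft_rest_s
    if (is.na(sched$rate_bpm[i])) sched$rate_bpm[i] <- cfg$breath_rate_bpm
  }
  # phase "test" keeps tidal_l NA: per-breath random amplitude draw
  sched
}

#' Generate a synthetic airflow signal with ground truth
#'
#' Builds a spirometer-style flow trace (positive flow = exhalation) as a
#' train of half-sine inhale/exhale cycles following the configured phase
#' schedule, plus forced maneuvers for `pft` phases (half-sine maximal inhale,
#' exponential forced exhale sustained 6 s). Per-breath tidal volumes carry
#' the configured jitter; the ground truth records, per breath, the window,
#' the exhaled and inhaled volumes actually generated (trapezoidal integral of
#' the signed flow lobes), and the breathing rate.
#'
#' @param config A [generator_config()].
#' @return List with `flow` (a `sampled_signal`, L/s), `truth` (a data frame
#'   of per-breath ground truth), and `annotations` (phase label table with
#'   `start_s`, `end_s`).
#' @export
generate_flow <- function(config) {
  cfg <- validate_generator_config(config)
  fs <- cfg$fs
  sched <- resolve_schedule(cfg)
  if (sum(sched$duration_s) > cfg$duration_s + 1e-9)
    stop("schedule total duration exceeds duration_s")
  n_total <- round(cfg$duration_s * fs)
  flow <- numeric(n_total)
  breaths <- list()
  ann <- list()
  free_levels <- cfg$amplitude_levels[c("shallow", "medium", "deep")]

  with_seed(cfg$seed, {
    pos <- 0L
    for (i in seq_len(nrow(sched))) {
      n_phase <- round(sched$duration_s[i] * fs)
      phase_end <- pos + n_phase
      ann[[i]] <- data.frame(phase = sched$phase[i], start_s = pos / fs,
                             end_s = phase_end / fs)
      if (sched$phase[i] == "pft") {
        w <- pft_maneuver_flow(cfg, fs)
        n_b <- length(w)
        if (pos + n_b > phase_end) n_b <- n_phase
        flow[(pos + 1):(pos + n_b)] <- w[seq_len(n_b)]
        breaths[[length(breaths) + 1L]] <- data.frame(
          start_idx = pos + 1L, end_idx = pos + n_b,
          phase = "pft", rate_bpm = NA_real_,
          scheduled_l = cfg$pft_depth_l)
        pos <- phase_end
        next
      }
      if (sched$phase[i] == "rest" ||
          (!is.na(sched$tidal_l[i]) && sched$tidal_l[i] == 0)) {
        pos <- phase_end
        next
      }
      rate <- sched$rate_bpm[i]
      n_half <- floor(fs * 30 / rate)
      n_breath <- 2L * n_half
      while (pos + n_breath <= phase_end) {
        tidal <- if (is.na(sched$tidal_l[i]))
          unname(sample(free_levels, 1)) else sched$tidal_l[i]
        v <- tidal * max(1 + cfg$amplitude_cv * stats::rnorm(1), 0.05)
        amp <- pi * v / (n_breath / fs)
        j <- seq_len(n_half) - 1
        half <- sin(pi * j / n_half)
        flow[(pos + 1):(pos + n_breath)] <- c(-amp * half, amp * half)
        breaths[[length(breaths) + 1L]] <- data.frame(
          start_idx = pos + 1L, end_idx = pos + n_breath,
          phase = sched$phase[i], rate_bpm = rate, scheduled_l = v)
        pos <- pos + n_breath
      }
      pos <- phase_end
    }
  })

  truth <- do.call(rbind, breaths)
  tt <- (seq_len(n_total) - 1) / fs
  truth$true_exhaled_l <- vapply(seq_len(nrow(truth)), function(k) {
    w <- truth$start_idx[k]:truth$end_idx[k]
    trapz1(tt[w], pmax(flow[w], 0))
  }, numeric(1))
  truth$true_inhaled_l <- vapply(seq_len(nrow(truth)), function(k) {
    w <- truth$start_idx[k]:truth$end_idx[k]
    trapz1(tt[w], pmax(-flow[w], 0))
  }, numeric(1))
  list(flow = sampled_signal(flow, fs, "L/s"),
       truth = truth,
       annotations = do.call(rbind, ann))
}

# One forced maneuver: half-sine maximal inhale, then exponential forced
# exhale sustained 6 s (flow D/tau * exp(-t/tau), so exhaled volume -> D).
pft_maneuver_flow <- function(cfg, fs) {
  d <- cfg$pft_depth_l * max(1 + cfg$amplitude_cv * stats::rnorm(1), 0.05)
  n_in <- round(cfg$pft_inhale_s * fs)
  amp <- pi * d / (2 * cfg$pft_inhale_s)
  inh <- -amp * sin(pi * (seq_len(n_in) - 1) / n_in)
  n_ex <- round(6 * fs)
  t_ex <- seq_len(n_ex) / fs
  exh <- d / cfg$pft_exhale_tau_s * exp(-t_ex / cfg$pft_exhale_tau_s)
  c(inh, exh)
}

#' Resistance response of a strain sensor to compartment volume
#'
#' Forward model of the piezo-resistive sensor: noise-free resistance is
#' `baseline + a * v(t)^b`, where `v(t)` is the compartment volume above the
#' end-expiratory level. Superimposed are additive Gaussian noise, integrated
#' random-walk baseline drift, and (optionally) a viscoelastic hysteresis
#' term: after a stretch exceeding `hysteresis_frac` of the recent excursion
#' range, the resistance returns to baseline along a first-order decay with
#' time constant `hysteresis_tau_s` instead of tracking the volume down.
#'
#' @param compartment_volume A `sampled_signal` in L (all values >= 0;
#'   negative volumes are an error — offset to end-expiratory zero first).
#' @param params Named vector `c(a = , b = )`.
#' @param baseline_ohm Unstrained resistance, ohm.
#' @param noise_sd_ohm,drift_rate_ohm_per_s,hysteresis_tau_s,hysteresis_frac
#'   Noise and artifact parameters as in [generator_config()].
#' @param seed Integer seed for the noise and drift draws.
#' @return A `sampled_signal` in ohm.
#' @export
strain_from_volume <- function(compartment_volume, params,
                               baseline_ohm = 4700,
                               noise_sd_ohm = 0, drift_rate_ohm_per_s = 0,
                               hysteresis_tau_s = 0, hysteresis_frac = 0.5,
                               seed = 1L) {
  v <- compartment_volume$values
  fs <- compartment_volume$fs
  if (any(v < -1e-9))
    stop("compartment volume must be >= 0 (offset to end-expiratory zero)")
  v <- pmax(v, 0)
  a <- params[["a"]]; b <- params[["b"]]
  if (b <= 0) stop("power exponent b must be > 0")
  s <- a * v^b
  if (hysteresis_tau_s > 0) s <- apply_hysteresis(s, fs, hysteresis_tau_s,
                                                  hysteresis_frac)
  n <- length(s)
  with_seed(seed, {
    noise <- if (noise_sd_ohm > 0) stats::rnorm(n, 0, noise_sd_ohm) else 0
    drift <- if (drift_rate_ohm_per_s > 0)
      cumsum(stats::rnorm(n, 0, drift_rate_ohm_per_s / sqrt(fs))) else 0
    sampled_signal(baseline_ohm + s + noise + drift, fs, "ohm")
  })
}

# Peak-hold-with-decay envelope: stretches above `frac` of the trailing
# excursion range set an envelope that decays with time constant tau; the
# output is the max of the instantaneous response and the envelope, so the
# sensor "remembers" large stretches and returns to baseline slowly.
apply_hysteresis <- function(s, fs, tau_s, frac) {
  n <- length(s)
  # trailing max of the stretch over ~30 s, on a decimated grid for speed
  step <- max(1L, floor(fs / 20))
  idx <- seq(1L, n, by = step)
  dec <- s[idx]
  w <- max(2L, round(30 * fs / step))
  run_max <- zoo::rollapplyr(zoo::zoo(dec), w, max, partial = TRUE)
  thr <- frac * as.numeric(run_max)
  thr_full <- rep(thr, each = step, length.out = n)
  decay <- exp(-1 / (tau_s * fs))
  out <- numeric(n)
  h <- 0
  for (i in seq_len(n)) {
    h <- h * decay
    si <- s[i]
    if (si > h && si >= thr_full[i]) h <- si
    out[i] <- if (h > si) h else si
  }
  out
}

#' Superimpose locomotion artifacts and synthesize accelerometer channels
#'
#' Adds sinusoidal artifacts at the step cadence and at half the cadence to
#' both strain channels (the half-cadence component emulates torso-torsion
#' strain seen during running, which the accelerometer does not carry), and
#' builds 3-axis accelerometer voltages whose dominant spectral component is
#' the cadence, with a DC gravity offset on the axis oriented into the torso.
#'
#' @param rib,abd `sampled_signal`s in ohm.
#' @param motion List with `cadence_hz`, `strain_artifact_amp_ohm`,
#'   `half_cadence_amp_ohm`, `accel_amp_v`.
#' @param seed Integer seed (random phases).
#' @return List with `rib`, `abd` (ohm) and `accel` (list of `ax`, `ay`, `az`
#'   `sampled_signal`s in V).
#' @export
add_motion <- function(rib, abd, motion, seed = 1L) {
  stopifnot(rib$fs == abd$fs, length(rib) == length(abd))
  fs <- rib$fs
  t <- signal_time(rib)
  f <- motion$cadence_hz
  a_str <- motion$strain_artifact_amp_ohm %||% 0
  a_half <- motion$half_cadence_amp_ohm %||% 0
  a_acc <- motion$accel_amp_v %||% 0
  with_seed(seed, {
    ph <- stats::runif(6, 0, 2 * pi)
    art <- function(k) a_str * sin(2 * pi * f * t + ph[k]) +
      a_half * sin(pi * f * t + ph[k + 1])
    rib2 <- reclothe(rib, rib$values + art(1))
    abd2 <- reclothe(abd, abd$values + art(3))
    accel <- list(
      ax = sampled_signal(0.3 * a_acc * sin(2 * pi * f * t + ph[5]) +
                            stats::rnorm(length(t), 0, 0.002), fs, "V"),
      ay = sampled_signal(a_acc * sin(2 * pi * f * t + ph[6]) +
                            stats::rnorm(length(t), 0, 0.002), fs, "V"),
      az = sampled_signal(1.5 + 0.4 * a_acc * sin(2 * pi * f * t + ph[5]) +
                            stats::rnorm(length(t), 0, 0.002), fs, "V"))
    list(rib = rib2, abd = abd2, accel = accel)
  })
}

#' Differential output of a quarter Wheatstone bridge
#'
#' `V = excitation * (R / (R + ref) - 1/2)`: zero when the bridge is balanced
#' (`R = ref`), approaching `excitation / 2` as `R` grows; monotone
#' increasing in `R`.
#'
#' @param resistance A `sampled_signal` (ohm) or numeric vector.
#' @param ref_ohm Bridge completion resistance, ohm (4.7 kOhm in the
#'   acquisition hardware this emulates).
#' @param excitation_v Bridge excitation voltage.
#' @return Same shape as the input, in V.
#' @export
bridge_voltage <- function(resistance, ref_ohm = 4700, excitation_v = 3) {
  f <- function(r) excitation_v * (r / (r + ref_ohm) - 0.5)
  if (inherits(resistance, "sampled_signal"))
    reclothe(resistance, f(resistance$values), units = "V")
  else f(resistance)
}

#' Generate a full synthetic multichannel recording
#'
#' Composes [generate_flow()], the lung-volume integral, the per-compartment
#' strain responses, optional locomotion artifacts, and the spirometer
#' voltage channel (flow divided by the flow constant) into a synchronized
#' recording with protocol annotations and per-breath ground truth (windows,
#' volumes, noise-free per-sensor resistance excursions).
#'
#' @param config A [generator_config()].
#' @return List with `recording` (class `respiration_recording`) and `truth`
#'   (per-breath ground-truth data frame, with `true_delta_r_rib` /
#'   `true_delta_r_abd` in ohm).
#' @examples
#' cfg <- generator_config(protocol_schedule("paced", rate_bpm = 20), seed = 7)
#' rec <- generate_recording(cfg)
#' rec$recording
#' head(rec$truth)
#' @export
generate_recording <- function(config) {
  cfg <- validate_generator_config(config)
  fs <- cfg$fs
  gf <- generate_flow(cfg)
  flow <- gf$flow
  tt <- signal_time(flow)
  # lung volume above end-expiratory level: integral of inspiratory flow
  v <- pmax(-cumtrapz1(tt, flow$values), 0)
  rib_v <- sampled_signal(cfg$rib_fraction * v, fs, "L")
  abd_v <- sampled_signal((1 - cfg$rib_fraction) * v, fs, "L")
  base_seed <- as.integer(cfg$seed %% 2147480000L)
  rib <- strain_from_volume(rib_v, cfg$power_params_rib, cfg$baseline_ohm,
                            cfg$noise_sd_ohm, cfg$drift_rate_ohm_per_s,
                            cfg$hysteresis_tau_s, cfg$hysteresis_frac,
                            seed = base_seed + 1L)
  abd <- strain_from_volume(abd_v, cfg$power_params_abd, cfg$baseline_ohm,
                            cfg$noise_sd_ohm, cfg$drift_rate_ohm_per_s,
                            cfg$hysteresis_tau_s, cfg$hysteresis_frac,
                            seed = base_seed + 2L)
  if (!is.null(cfg$motion)) {
    m <- add_motion(rib, abd, cfg$motion, seed = base_seed + 3L)
    rib <- m$rib; abd <- m$abd; accel <- m$accel
  } else {
    n <- length(flow)
    accel <- with_seed(base_seed + 3L, list(
      ax = sampled_signal(stats::rnorm(n, 0, 0.002), fs, "V"),
      ay = sampled_signal(stats::rnorm(n, 0, 0.002), fs, "V"),
      az = sampled_signal(1.5 + stats::rnorm(n, 0, 0.002), fs, "V")))
  }
  truth <- gf$truth
  a_r <- cfg$power_params_rib; a_a <- cfg$power_params_abd
  vmax <- vapply(seq_len(nrow(truth)), function(k)
    max(v[truth$start_idx[k]:truth$end_idx[k]]), numeric(1))
  truth$true_delta_r_rib <- a_r[["a"]] * (cfg$rib_fraction * vmax)^a_r[["b"]]
  truth$true_delta_r_abd <- a_a[["a"]] * ((1 - cfg$rib_fraction) * vmax)^a_a[["b"]]

  channels <- data.frame(time_s = tt,
                         spiro_v = flow$values / cfg$flow_constant_l_per_sv,
                         rib_ohm = rib$values,
                         abd_ohm = abd$values,
                         ax_v = accel$ax$values,
                         ay_v = accel$ay$values,
                         az_v = accel$az$values)
  rec <- structure(list(channels = channels, fs = fs,
                        annotations = gf$annotations,
                        flow_constant_l_per_sv = cfg$flow_constant_l_per_sv,
                        seed = cfg$seed,
                        config_hash = config_hash(unclass(cfg))),
                   class = "respiration_recording")
  list(recording = rec, truth = truth)
}

#' @export
print.respiration_recording <- function(x, ...) {
  cat(sprintf("<respiration_recording> %d samples @ %g Hz (%.1f s), %d phases\n",
              nrow(x$channels), x$fs, nrow(x$channels) / x$fs,
              nrow(x$annotations)))
  cat("  phases:", paste(x$annotations$phase, collapse = ", "), "\n")
  cat("  seed:", x$seed, " config:", x$config_hash, "\n")
  invisible(x)
}

#' Extract one channel of a recording as a sampled signal
#'
#' @param rec A `respiration_recording`.
#' @param channel Column name, e.g. `"rib_ohm"`, `"spiro_v"`, `"ay_v"`.
#' @return A `sampled_signal` with units inferred from the column suffix.
#' @export
recording_channel <- function(rec, channel) {
  stopifnot(inherits(rec, "respiration_recording"),
            channel %in% names(rec$channels))
  units <- c(v = "V", ohm = "ohm", s = "s")[sub(".*_", "", channel)]
  sampled_signal(rec$channels[[channel]], rec$fs,
                 if (is.na(units)) "" else units)
}
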