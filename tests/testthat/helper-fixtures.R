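# Shared fixtures: small, fast generator configurations used across tests.

# Three-amplitude calibration cohort (30 breaths per amplitude at 15 bpm).
cohort_schedule <- function(duration_s = 120) {
  data.frame(phase = c("shallow", "medium", "deep"),
             duration_s = duration_s, tidal_l = NA_real_, rate_bpm = 15)
}

# Free-order test session (breath amplitudes drawn at random per breath).
test_schedule <- function(duration_s = 240) {
  data.frame(phase = "test", duration_s = duration_s, tidal_l = NA_real_,
             rate_bpm = 15)
}

# A short paced recording, preprocessed, with its ground truth.
paced_case <- function(rate_bpm, seed, duration_s = NULL, fs = 1000, ...) {
  cfg <- generator_config(protocol_schedule("paced", rate_bpm = rate_bpm,
                                            duration_s = duration_s),
                          fs = fs, seed = seed, ...)
  gen <- generate_recording(cfg)
  prep <- preprocess_recording(gen$recording)
  list(cfg = cfg, recording = gen$recording, truth = gen$truth, prep = prep)
}

# Pure sinusoid as a sampled signal.
sine_signal <- function(freq_hz, duration_s, fs = 1000, amplitude = 1,
                        units = "") {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  sampled_signal(amplitude * sin(2 * pi * freq_hz * t), fs, units)
}

default_motion <- function(cadence_hz = 2.09) {
  list(cadence_hz = cadence_hz, strain_artifact_amp_ohm = 0.3,
       half_cadence_amp_ohm = 0.1, accel_amp_v = 0.5)
}
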