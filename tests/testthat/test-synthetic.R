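test_that("generated flow conserves scheduled tidal volumes and breath counts", {
  # 20 bpm for 60 s, no jitter: exactly 20 breaths, each exhaling 0.8 L
  cfg <- generator_config(protocol_schedule("paced", rate_bpm = 20),
                          amplitude_cv = 0, seed = 1)
  gf <- generate_flow(cfg)
  expect_equal(nrow(gf$truth), 20)
  expect_equal(gf$truth$scheduled_l, rep(0.8, 20))
  # conservation: exhale-window integral matches the schedule (quadrature only)
  expect_lt(max(abs(gf$truth$true_exhaled_l - gf$truth$scheduled_l) /
                  gf$truth$scheduled_l), 1e-3)
  # mean peak-to-peak spacing of breath windows is the 3 s period
  expect_equal(mean(diff(gf$truth$start_idx)) / cfg$fs, 3.0)

  # single breath at 15 bpm, tidal 1.0 L
  one <- generator_config(data.frame(phase = "paced", duration_s = 4,
                                     tidal_l = 1.0, rate_bpm = 15),
                          amplitude_cv = 0, seed = 2)
  g1 <- generate_flow(one)
  expect_equal(nrow(g1$truth), 1)
  expect_equal(g1$truth$true_exhaled_l, 1.0, tolerance = 1e-3)
})

test_that("half-sine exhale integral matches the closed form 2*A*T/pi", {
  # flow = A*sin(2*pi*t/4) imposed for one 4 s cycle, A = 1 L/s:
  # each half-sine lobe carries 4/pi ~ 1.2732 L
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  fl <- sampled_signal(sin(2 * pi * t / 4), fs, "L/s")
  vol <- pracma::trapz(t[1:2001], pmax(fl$values[1:2001], 0))
  expect_equal(vol, 4 / pi, tolerance = 1e-6)
})

test_that("schedules longer than the recording are rejected", {
  expect_error(generator_config(protocol_schedule("calibration"),
                                duration_s = 100),
               "exceeds duration_s")
  expect_error(generator_config(protocol_schedule("paced"),
                                rib_fraction = 1.5), "rib_fraction")
})

test_that("strain response evaluates the power law and is exact when noiseless", {
  fs <- 100
  v <- sampled_signal(c(rep(0, 50), rep(1, 50)), fs, "L")
  r <- strain_from_volume(v, c(a = 2, b = 1.5), baseline_ohm = 100)
  expect_equal(r$values[1:50], rep(100, 50))
  expect_equal(r$values[51:100], rep(102, 50))  # dR = 2 * 1^1.5

  # zero volume everywhere: resistance identically at baseline
  v0 <- sampled_signal(rep(0, 100), fs, "L")
  expect_equal(strain_from_volume(v0, c(a = 2, b = 1.2),
                                  baseline_ohm = 50)$values, rep(50, 100))

  # negative compartment volume is a caller error
  vneg <- sampled_signal(c(-0.1, 0.1), fs, "L")
  expect_error(strain_from_volume(vneg, c(a = 2, b = 1.2)), ">= 0")
})

test_that("strain noise SD is recovered from generated residuals", {
  fs <- 1000
  v <- sampled_signal(rep(0.5, 2e4), fs, "L")
  r <- strain_from_volume(v, c(a = 2, b = 1.4), baseline_ohm = 100,
                          noise_sd_ohm = 0.05, seed = 31)
  clean <- 100 + 2 * 0.5^1.4
  resid_sd <- sd(r$values - clean)
  expect_lt(abs(resid_sd - 0.05) / 0.05, 0.2)
})

test_that("seed determinism holds across all generators", {
  cfg <- generator_config(protocol_schedule("paced", rate_bpm = 20,
                                            duration_s = 12),
                          fs = 200, seed = 9)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(a$truth, b$truth)
  # and a different seed changes the data
  cfg2 <- generator_config(protocol_schedule("paced", rate_bpm = 20,
                                             duration_s = 12),
                           fs = 200, seed = 10)
  expect_false(identical(generate_recording(cfg2)$recording$channels,
                         a$recording$channels))
})

test_that("motion artifacts land at cadence and half-cadence, accel at cadence", {
  fs <- 500
  n <- 60 * fs
  rib <- sampled_signal(rep(100, n), fs, "ohm")
  abd <- sampled_signal(rep(100, n), fs, "ohm")
  m <- add_motion(rib, abd, default_motion(cadence_hz = 3.05), seed = 5)
  sp_ay <- respstrain:::dominant_frequency(m$accel$ay$values, fs, 0.25, 10)
  expect_equal(sp_ay, 3.05, tolerance = 1 / 60 + 1e-9)
  # strain spectrum has a half-cadence peak absent from the accelerometer
  amp_at <- function(x, f0) {
    sp <- respstrain:::amplitude_spectrum(x, fs)
    max(sp$amplitude[abs(sp$freq_hz - f0) < 2 / 60])
  }
  expect_gt(amp_at(m$rib$values, 1.525), 10 * amp_at(m$accel$ay$values, 1.525))

  # zero amplitudes: strain channels unchanged exactly
  m0 <- add_motion(rib, abd, list(cadence_hz = 2, strain_artifact_amp_ohm = 0,
                                  half_cadence_amp_ohm = 0, accel_amp_v = 0),
                   seed = 5)
  expect_equal(m0$rib$values, rib$values)
  expect_equal(m0$abd$values, abd$values)
})

test_that("bridge voltage is the quarter-bridge formula and monotone", {
  expect_equal(bridge_voltage(4700, ref_ohm = 4700, excitation_v = 3), 0)
  expect_equal(bridge_voltage(9400, ref_ohm = 4700, excitation_v = 3), 0.5)
  expect_equal(bridge_voltage(1e12, ref_ohm = 4700, excitation_v = 3), 1.5,
               tolerance = 1e-6)
  r <- seq(1000, 10000, by = 100)
  expect_true(all(diff(bridge_voltage(r)) > 0))
})

test_that("recording channels are aligned and spirometer voltage inverts to flow", {
  cfg <- generator_config(protocol_schedule("paced", rate_bpm = 20,
                                            duration_s = 12),
                          fs = 200, seed = 4)
  gen <- generate_recording(cfg)
  gf <- generate_flow(cfg)
  expect_equal(gen$recording$channels$spiro_v * cfg$flow_constant_l_per_sv,
               gf$flow$values)
  expect_equal(nrow(gen$recording$channels), round(cfg$duration_s * cfg$fs))
})

test_that("PFT protocol produces five annotated forced maneuvers", {
  cfg <- generator_config(protocol_schedule("pft"), fs = 200, seed = 6)
  gen <- generate_recording(cfg)
  expect_equal(sum(gen$recording$annotations$phase == "pft"), 5)
  expect_equal(sum(gen$recording$annotations$phase == "rest"), 4)
  expect_equal(nrow(gen$truth), 5)
  # each maneuver exhales close to its inhaled depth
  expect_equal(gen$truth$true_exhaled_l, gen$truth$true_inhaled_l,
               tolerance = 0.02)
})

test_that("recording and generator config round-trip through disk formats", {
  cfg <- generator_config(protocol_schedule("paced", rate_bpm = 20,
                                            duration_s = 9), fs = 100,
                          seed = 3)
  gen <- generate_recording(cfg)
  csv <- tempfile(fileext = ".csv")
  write_recording(gen$recording, csv)
  back <- read_recording(csv)
  expect_equal(back$channels, gen$recording$channels, tolerance = 1e-12)
  expect_equal(back$fs, gen$recording$fs)
  expect_equal(back$annotations$phase, gen$recording$annotations$phase)

  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(protocol = "paced", rate_bpm = 20, fs = 100,
                        seed = 3, noise_sd_ohm = 0.01), yml)
  cfg2 <- read_generator_config(yml)
  expect_equal(cfg2$noise_sd_ohm, 0.01)
  expect_equal(cfg2$fs, 100)
  expect_s3_class(cfg2, "generator_config")
})
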