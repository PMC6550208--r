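test_that("despike removes isolated spikes and passes smooth signals", {
  fs <- 1000
  x <- rep(1, 2000)
  expect_equal(despike(sampled_signal(x, fs, "V"))$values, x)

  spiky <- x; spiky[700] <- 100
  out <- despike(sampled_signal(spiky, fs, "V"))
  expect_equal(out$values[700], 1, tolerance = 1e-9)
  expect_equal(out$values[-700], x[-700])

  s <- sine_signal(0.3, 10, fs)
  out2 <- despike(s)
  expect_lt(max(abs(out2$values - s$values)), 0.01)  # < 1% of amplitude

  expect_error(despike(sampled_signal(x, 10, "V"), window_s = 0.1),
               "at least 3 samples")
})

test_that("voltage-to-flow scaling applies the spirometer constant", {
  v <- sampled_signal(c(1, 0, -0.5), 10, "V")
  expect_equal(voltage_to_flow(v, 2.04)$values, c(2.04, 0, -1.02))
  expect_equal(voltage_to_flow(v, 1.0)$values, v$values)
  expect_equal(voltage_to_flow(v)$units, "L/s")
})

test_that("flow integration is the cumulative trapezoid", {
  fs <- 100
  q <- sampled_signal(rep(1, 2 * fs + 1), fs, "L/s")
  vol <- integrate_flow(q)
  expect_equal(vol$values[1], 0)
  expect_equal(vol$values[length(vol$values)], 2.0)

  # full sine cycle integrates to ~0; half lobe of A*sin(pi*t/2) to 4/pi
  s <- sine_signal(0.25, 4, 1000, units = "L/s")
  expect_lt(abs(integrate_flow(s)$values[4000]), 1e-4)
  t <- seq(0, 2, by = 1e-3)
  h <- sampled_signal(sin(pi * t / 2), 1000, "L/s")
  expect_equal(integrate_flow(h)$values[2001], 4 / pi, tolerance = 1e-6)
})

test_that("zero-phase low-pass preserves the passband and kills the stopband", {
  fs <- 1000
  s <- sine_signal(0.3, 30, fs)
  out <- lowpass(s, 20)
  mid <- 5000:25000
  expect_lt(max(abs(out$values[mid] - s$values[mid])), 0.01)

  # 50 Hz component attenuated by > 40 dB
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  mix <- sampled_signal(sin(2 * pi * 0.3 * t) + sin(2 * pi * 50 * t), fs, "")
  filt <- lowpass(mix, 20)
  amp50 <- function(x) {
    sp <- respstrain:::amplitude_spectrum(x, fs)
    max(sp$amplitude[abs(sp$freq_hz - 50) < 0.1])
  }
  expect_lt(amp50(filt$values) / amp50(mix$values), 10^(-40 / 20))

  # DC gain is 1
  dc <- sampled_signal(rep(2.5, 5000), fs, "")
  expect_equal(lowpass(dc, 20)$values, dc$values, tolerance = 1e-6)

  expect_error(lowpass(s, 600), "fs/2")
})

test_that("hysteresis jump correction flattens baseline steps", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  breathing <- 100 + pmax(sin(2 * pi * t / 4), 0)
  r0 <- sampled_signal(breathing, fs, "ohm")
  expect_equal(correct_hysteresis(r0, 1)$values, breathing, tolerance = 0.1)

  # one +5 ohm baseline step mid-recording
  stepped <- breathing + 5 * (t >= 30)
  out <- correct_hysteresis(sampled_signal(stepped, fs, "ohm"), 1)
  pre <- min(out$values[t > 20 & t < 28])
  post <- min(out$values[t > 34 & t < 42])
  expect_lt(abs(post - pre), 0.1)

  # two successive +-5 ohm steps: both removed, no net drift
  doubled <- breathing + 5 * (t >= 20) - 5 * (t >= 40)
  out2 <- correct_hysteresis(sampled_signal(doubled, fs, "ohm"), 1)
  expect_lt(abs(min(out2$values[t > 45 & t < 55]) -
                  min(out2$values[t > 5 & t < 15])), 0.1)
  expect_lt(abs(min(out2$values[t > 25 & t < 35]) -
                  min(out2$values[t > 5 & t < 15])), 0.1)
})

test_that("motion filter recovers the respiration peak and returns its cutoff", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  breath <- sin(2 * pi * 0.33 * t)
  artifact <- 0.8 * sin(2 * pi * 2.0 * t)
  r <- sampled_signal(100 + breath + artifact, fs, "ohm")
  accel <- sampled_signal(0.5 * sin(2 * pi * 2.0 * t), fs, "V")
  mf <- motion_filter(r, accel)
  expect_equal(mf$cadence_hz, 2.0, tolerance = 1 / 60 + 1e-9)
  expect_lt(mf$cutoff_hz, mf$cadence_hz)
  got <- respstrain:::dominant_frequency(mf$signal$values - 100, fs, 0.05, 3)
  expect_equal(got, 0.33, tolerance = 1 / 60 + 1e-9)

  # artifact-free strain passes nearly unchanged (passband integrity)
  r2 <- sampled_signal(100 + breath, fs, "ohm")
  mf2 <- motion_filter(r2, accel)
  mid <- 5000:25000
  expect_lt(max(abs(mf2$signal$values[mid] - r2$values[mid])), 0.02)

  # pure-noise accelerometer: no locomotion detected
  set.seed(1)
  noise <- sampled_signal(rnorm(length(t), 0, 0.01), fs, "V")
  expect_error(motion_filter(r, noise), "no locomotion")
})

test_that("motion filter spares components below half its cutoff", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  accel <- sampled_signal(0.5 * sin(2 * pi * 2.4 * t), fs, "V")
  for (f0 in c(0.2, 0.4, 0.55)) {
    s <- sampled_signal(sin(2 * pi * f0 * t), fs, "ohm")
    mf <- motion_filter(s, accel)
    if (f0 <= 0.5 * mf$cutoff_hz) {
      mid <- 5000:25000
      expect_lt(max(abs(mf$signal$values[mid] - s$values[mid])), 0.02)
    }
  }
})

test_that("detrending removes exactly the best-fit line", {
  fs <- 100
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  ramp <- sampled_signal(2 + 0.1 * t, fs, "")
  expect_lt(max(abs(detrend(ramp)$values)), 1e-9)

  # cosine over whole periods: zero mean and, by symmetry, zero OLS slope
  cosine <- sampled_signal(cos(2 * pi * 0.5 * t), fs, "")
  expect_equal(detrend(cosine)$values, cosine$values, tolerance = 2e-3)

  mix <- sampled_signal(sin(2 * pi * 0.5 * t) + 3 * t, fs, "")
  out <- detrend(mix)
  refit <- coef(lm(out$values ~ t))[2]
  expect_lt(abs(refit) / 3, 1e-9)
})

test_that("preprocessing preserves length and sampling rate", {
  s <- sine_signal(0.3, 10, 200)
  for (op in list(function(x) despike(x),
                  function(x) lowpass(x, 20),
                  function(x) detrend(x),
                  function(x) correct_hysteresis(x),
                  function(x) integrate_flow(x))) {
    out <- op(s)
    expect_equal(length(out$values), length(s$values))
    expect_equal(out$fs, s$fs)
  }
})

test_that("integration inverts differentiation on smooth signals", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.4 * t) + 0.3 * cos(2 * pi * 0.15 * t)
  dx <- c(0, diff(x)) * fs  # forward-difference derivative
  back <- integrate_flow(sampled_signal(dx, fs, "L/s"))$values + x[1]
  expect_lt(max(abs(back - x)), 5e-3)
})
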