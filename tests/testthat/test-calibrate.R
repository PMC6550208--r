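test_that("power fit recovers exact parameters from noiseless pairs", {
  dr <- seq(0.2, 3, length.out = 12)
  pm <- fit_power(dr, 2 * dr^1.5)
  expect_equal(pm$a, 2, tolerance = 1e-9)
  expect_equal(pm$b, 1.5, tolerance = 1e-9)
  expect_equal(pm$r2, 1, tolerance = 1e-9)
  expect_equal(pm$r2_log, 1, tolerance = 1e-9)

  lin <- fit_power(dr, dr)  # linear data: a = b = 1
  expect_equal(lin$a, 1, tolerance = 1e-9)
  expect_equal(lin$b, 1, tolerance = 1e-9)
})

test_that("power fit handles noise and rejects degenerate input", {
  set.seed(41)
  dr <- runif(60, 0.3, 2.5)
  v <- pmax(1.3 * dr^1.4 + rnorm(60, 0, 0.05), 0.05)
  pm <- fit_power(dr, v)
  expect_lt(abs(pm$b - 1.4), 0.1)
  expect_gt(pm$r2, 0.95)

  expect_error(fit_power(c(-1, 1, 2, 3, 4), 1:5), "positive")
  expect_error(fit_power(rep(1, 6), 1:6), "constant")
  expect_error(fit_power(1:4, 1:4), "at least 5")
})

test_that("linearization maps excursions through the power model", {
  pm <- structure(list(a = 2, b = 1.5), class = "power_model")
  expect_equal(linearize(0, pm), 0)
  expect_equal(linearize(1, pm), 2)
  expect_equal(linearize(1, pm, transform = "exponent"), 1)
  expect_error(linearize(-0.1, pm), ">= 0")

  # linearize-then-regress on noiseless data: slope 1, intercept 0
  dr <- seq(0.2, 3, length.out = 20)
  v <- 0.8 * dr^1.2
  pm2 <- fit_power(dr, v)
  fit <- lm(v ~ linearize(dr, pm2))
  expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-6)
})

test_that("the regression plane reproduces exact mixtures", {
  set.seed(7)
  lin_rib <- runif(30, 0.2, 2)
  lin_abd <- runif(30, 0.2, 2)
  vol <- 0.4 * lin_rib + 0.6 * lin_abd
  fit <- fit_mlr(lin_rib, lin_abd, vol)
  expect_equal(coef(fit), c(beta0 = 0, beta_rib = 0.4, beta_abd = 0.6),
               tolerance = 1e-9)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)

  # single-compartment case: zero abdomen channel drops out
  fit1 <- fit_mlr(lin_rib, rep(0, 30), lin_rib)
  expect_equal(unname(coef(fit1)), c(0, 1, 0), tolerance = 1e-9)

  # exact duplicates are a rank-deficient design
  expect_error(fit_mlr(lin_rib, lin_rib, vol), "collinear")
  expect_error(fit_mlr(lin_rib[1:5], lin_abd[1:5], vol[1:5]), "at least 6")
})

test_that("the full calibrate-predict loop recovers noiseless volumes", {
  cfg <- generator_config(cohort_schedule(duration_s = 60),
                          noise_sd_ohm = 0, drift_rate_ohm_per_s = 0,
                          seed = 44)
  gen <- generate_recording(cfg)
  prep <- preprocess_recording(gen$recording)
  br <- add_delta_r(segment_breaths(prep$flow), prep$rib, prep$abd)
  fit <- kono_mead(exhaled_l ~ dr_rib_ohm + dr_abd_ohm, br)
  pred <- predict(fit, br)
  expect_lt(max(abs(pred - gen$truth$true_exhaled_l) /
                  gen$truth$true_exhaled_l), 0.01)
})

test_that("the two-sensor regression fits at least as well as either sensor", {
  cfg <- generator_config(cohort_schedule(duration_s = 60), seed = 45)
  gen <- generate_recording(cfg)
  prep <- preprocess_recording(gen$recording)
  br <- add_delta_r(segment_breaths(prep$flow), prep$rib, prep$abd)
  fit <- kono_mead(exhaled_l ~ dr_rib_ohm + dr_abd_ohm, br)
  # small allowance for the adjusted-R2 degrees-of-freedom penalty
  expect_gte(fit$adj_r2,
             max(fit$rib_power$r2, fit$abd_power$r2) - 1e-4)
})

test_that("regression SEE shrinks as generator noise shrinks", {
  sees <- vapply(c(0.2, 0.05, 0), function(sd) {
    cfg <- generator_config(cohort_schedule(duration_s = 60),
                            noise_sd_ohm = sd, drift_rate_ohm_per_s = 0,
                            seed = 46)
    gen <- generate_recording(cfg)
    prep <- preprocess_recording(gen$recording)
    br <- add_delta_r(segment_breaths(prep$flow), prep$rib, prep$abd)
    kono_mead(exhaled_l ~ dr_rib_ohm + dr_abd_ohm, br)$see
  }, numeric(1))
  expect_true(all(diff(sees) < 0))
})

test_that("predictions are nondecreasing in each excursion when betas >= 0", {
  dr <- seq(0.3, 2.5, length.out = 40)
  set.seed(48)
  v <- 0.5 * dr^1.3 + 0.4 * dr^1.1 + rnorm(40, 0, 0.01)
  fit <- kono_mead(volume ~ rib + abd,
                   data.frame(volume = pmax(v, 0.05), rib = dr,
                              abd = dr * runif(40, 0.9, 1.1)))
  if (all(coef(fit)[-1] >= 0)) {
    grid <- seq(0.3, 2.5, length.out = 25)
    p_rib <- predict(fit, data.frame(rib = grid, abd = rep(1, 25)))
    p_abd <- predict(fit, data.frame(rib = rep(1, 25), abd = grid))
    expect_true(all(diff(p_rib) >= -1e-12))
    expect_true(all(diff(p_abd) >= -1e-12))
  }
  # prediction floors at zero
  expect_gte(predict(fit, data.frame(rib = 0, abd = 0)), 0)
})

test_that("calibration models survive a JSON round trip", {
  set.seed(49)
  dr_rib <- runif(30, 0.2, 2)
  dr_abd <- runif(30, 0.2, 2)
  vol <- pmax(0.5 * dr_rib^1.4 + 0.5 * dr_abd^1.2 + rnorm(30, 0, 0.02), 0.05)
  fit <- kono_mead(volume ~ dr_rib + dr_abd,
                   data.frame(volume = vol, dr_rib = dr_rib,
                              dr_abd = dr_abd))
  path <- tempfile(fileext = ".json")
  write_calibration(fit, path)
  back <- read_calibration(path)
  nd <- data.frame(dr_rib = c(0.5, 1.5), dr_abd = c(0.6, 1.1))
  expect_equal(predict(back, nd), predict(fit, nd), tolerance = 1e-12)
  expect_equal(back$adj_r2, fit$adj_r2, tolerance = 1e-12)
})
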