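test_that("phantom construction is uniform over the gate, exact in count, and seeded", {
  params <- acquisition_params(gate_upper = 20, gate_lower = 40)
  ph <- build_phantom(params, density = 10, seed = 1, margin = 0)
  expect_length(ph$scatterer_depths, 200)  # density * span
  expect_true(all(ph$scatterer_depths >= 20 & ph$scatterer_depths <= 40))

  ph2 <- build_phantom(params, density = 10, seed = 1, margin = 0)
  expect_identical(ph, ph2)

  ph3 <- build_phantom(params, density = 10, seed = 2, margin = 0)
  expect_false(identical(ph$scatterer_depths, ph3$scatterer_depths))

  phm <- build_phantom(params, density = 5, seed = 1, margin = 2)
  expect_true(all(phm$scatterer_depths >= 18 & phm$scatterer_depths <= 42))

  expect_error(build_phantom(params, density = 0),
               class = "twitchtdi_invalid_argument")
  expect_error(build_phantom(params, density = -3),
               class = "twitchtdi_invalid_argument")
})

test_that("twitch displacement is compactly supported, isometric, with one velocity zero-crossing", {
  kin <- default_kin()
  t_end <- kin$onset_time + kin$total_duration

  expect_equal(twitch_motion(kin, c(0, 0.1, kin$onset_time)), c(0, 0, 0))
  expect_equal(twitch_motion(kin, t_end), 0, tolerance = 1e-12)

  # isometric closure at several depths, analytically
  for (d in c(0.016, 0.025, 0.034)) {
    expect_lt(abs(twitch_motion(kin, t_end, depth = d, depth_center = 0.025)),
              1e-12)
  }

  # numerical derivative of displacement crosses zero at onset + expansion
  h <- 1e-6
  tz <- kin$onset_time + kin$expansion_duration
  dv <- (twitch_motion(kin, tz + h) - twitch_motion(kin, tz - h)) / (2 * h)
  expect_lt(abs(dv), 1e-6)

  # exactly one sign change of velocity in (onset, end)
  tt <- seq(kin$onset_time + 1e-4, t_end - 1e-4, by = 1e-4)
  v <- twitch_velocity(kin, tt)
  expect_equal(sum(diff(sign(v)) != 0), 1)

  # velocity integrates to displacement (trapezoid check)
  disp <- pracma::trapz(tt, v)
  expect_equal(disp, 0, tolerance = 1e-6)
})

test_that("stimulation train reproduces the cyclic fatiguing protocol timing", {
  st <- stimulation_train()  # 0.12 + 0.5 + 0.12 + 0.26 s, 60 cycles, 50 Hz
  tr <- make_stimulation_train(st)
  expect_equal(tr$cycle_period, 1.0)
  expect_equal(tr$train_duration, 60)

  # 50 Hz hold -> 20 ms main pulse interval
  intervals <- diff(tr$pulse_times[tr$pulse_times < st$ramp_up + st$hold])
  expect_equal(unique(round(intervals, 9)), 0.02)

  # envelope bounded by the working amplitude, reaches it during hold
  expect_lte(max(tr$envelope$current_ma), st$amplitude)
  hold_idx <- tr$envelope$time_s %% 1 >= 0.12 & tr$envelope$time_s %% 1 < 0.62
  expect_true(all(tr$envelope$current_ma[hold_idx] == st$amplitude))
  # rest is silent
  rest_idx <- tr$envelope$time_s %% 1 >= 0.75 & tr$envelope$time_s %% 1 < 0.99
  expect_true(all(tr$envelope$current_ma[rest_idx] == 0))

  expect_error(stimulation_train(ramp_up = -0.1),
               class = "twitchtdi_invalid_argument")
})

test_that("recovery multipliers follow the capped power law and increase monotonically", {
  fat <- fatigue_model(recovery_b0 = 0.614, recovery_b1 = 0.236)
  m <- recovery_multiplier(fat, 1:5)
  expect_equal(m, 0.614 * (1:5)^0.236)
  expect_true(all(diff(m) > 0))
  expect_true(all(m <= 1))
  # cap engages for large k
  expect_equal(recovery_multiplier(fat, 1000), 1)
})

test_that("noiseless torque is an exact linear map of the true features", {
  fat <- fatigue_model(torque_weights = c(peak_velocity_mps = 1),
                       torque_noise_sd = 0, feature_jitter_cv = 0)
  spec <- synthetic_study(n_subjects = 2, n_rounds = 1, seed = 4,
                          subject_amplitude_cv = 0.2)
  st <- generate_study(spec, fat, level = "features")
  expect_equal(st$torque_nm, st$true_peak_velocity_mps)
})

test_that("a zero post-fatigue drop yields twitches identical to baseline", {
  fat <- fatigue_model(post_fatigue_drop = 0, duration_inflation = 0,
                       feature_jitter_cv = 0, torque_noise_sd = 0)
  st <- generate_study(synthetic_study(n_subjects = 1, n_rounds = 2, seed = 9),
                       fat, level = "features")
  for (col in paste0("true_", feature_names5)) {
    expect_equal(unique(st[[col]]), st[[col]][1])
  }
  expect_equal(unique(st$multiplier), 1)
})

test_that("identical seeds reproduce the study bit for bit, different seeds do not", {
  spec <- synthetic_study(n_subjects = 2, n_rounds = 1, seed = 7)
  a <- generate_study(spec, level = "waveform")
  b <- generate_study(spec, level = "waveform")
  expect_identical(a, b)
  d <- generate_study(synthetic_study(n_subjects = 2, n_rounds = 1, seed = 8),
                      level = "waveform")
  expect_false(identical(a$torque_nm, d$torque_nm))
})

test_that("features extracted from the noiseless analytic profile match stored ground truth", {
  fat <- fatigue_model(feature_jitter_cv = 0, torque_noise_sd = 0)
  spec <- synthetic_study(n_subjects = 1, n_rounds = 1, seed = 3,
                          subject_amplitude_cv = 0, velocity_noise_sd = 0)
  st <- generate_study(spec, fat, level = "waveform")
  fe <- measure_study_features(st)
  # closed-form ground truth vs grid-based extraction of the exact waveform
  expect_equal(fe$peak_velocity_mps, fe$true_peak_velocity_mps,
               tolerance = 1e-3)
  expect_equal(fe$peak_vti_m, fe$true_peak_vti_m, tolerance = 1e-3)
  expect_true(all(abs(fe$time_to_zero_s - fe$true_time_to_zero_s) <= 2e-3))
  expect_true(all(abs(fe$total_duration_s - fe$true_total_duration_s) <= 5e-3))
})
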