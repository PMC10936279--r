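test_that("spectral entropy separates broadband noise from tonal and constant signals", {
  set.seed(1)
  noise <- rnorm(3000)
  ent_n <- spectral_entropy(noise)$entropy

  # Monte-Carlo oracle for the flat-spectrum limit: normalized entropy of
  # iid exponential periodogram ordinates over the positive-frequency bins
  n_bins <- 164 %/% 2
  mc <- replicate(400, {
    p <- stats::rexp(n_bins)
    p <- p / sum(p)
    -sum(p * log(p)) / log(n_bins)
  })
  expect_equal(mean(ent_n), mean(mc), tolerance = 0.02)
  expect_true(all(ent_n > 0.8))

  tone <- sin(2 * pi * 50 * (1:3000) / 1000)
  expect_true(all(spectral_entropy(tone)$entropy < 0.3))

  expect_equal(unique(spectral_entropy(rep(2, 500))$entropy), 0)

  expect_error(spectral_entropy(rnorm(100), window = 164),
               class = "twitchtdi_invalid_argument")
})

test_that("three-point segmentation locates onset, zero-crossing and end of a half-sine twitch", {
  wf <- half_sine_waveform(A = 0.02, D = 0.2)
  seg <- segment_twitch(wf, stim_time = 0)
  expect_lt(abs(seg$t_onset - 0), 2e-3)
  expect_lt(abs(seg$t_zero - 0.1), 2e-3)
  expect_lt(abs(seg$t_end - 0.2), 2e-3)
  expect_true(seg$t_onset < seg$t_zero && seg$t_zero < seg$t_end)
})

test_that("segmentation fails loudly on silent waveforms and missing crossings", {
  t <- seq(0, 0.6, by = 1e-3)
  zero <- new_velocity_waveform(rep(0, length(t)), t, 1000)
  expect_error(segment_twitch(zero, 0.1), class = "twitchtdi_no_twitch")

  # monotone ramp: onset is found but velocity never crosses zero
  ramp <- new_velocity_waveform(seq(0, 0.02, length.out = length(t)), t, 1000)
  expect_error(segment_twitch(ramp, 0.1),
               class = "twitchtdi_segmentation_failure")
})

test_that("segmentation is polarity invariant and time-shift equivariant", {
  wf <- half_sine_waveform()
  seg <- segment_twitch(wf, 0)

  neg <- new_velocity_waveform(-wf$values, wf$times, wf$rate)
  seg_neg <- segment_twitch(neg, 0)
  expect_equal(unclass(seg_neg), unclass(seg))

  for (shift in c(0.05, 0.213)) {
    shifted <- new_velocity_waveform(wf$values, wf$times + shift, wf$rate)
    seg_s <- segment_twitch(shifted, shift)
    expect_equal(seg_s$t_onset - seg$t_onset, shift, tolerance = 1e-9)
    expect_equal(seg_s$t_zero - seg$t_zero, shift, tolerance = 1e-9)
    expect_equal(seg_s$t_end - seg$t_end, shift, tolerance = 1e-9)
  }
})

test_that("segmentation ordering holds across randomly drawn noisy twitches", {
  set.seed(42)
  for (i in 1:20) {
    kin <- twitch_kinematics(
      onset_time = runif(1, 0.12, 0.2),
      expansion_duration = runif(1, 0.05, 0.15),
      total_duration = runif(1, 0.2, 0.35),
      peak_velocity_amplitude = runif(1, 0.005, 0.04))
    wf <- analytic_waveform(kin, duration = 1)
    wf$values <- wf$values + rnorm(length(wf$values), 0, 5e-4)
    seg <- segment_twitch(wf, stim_time = 0.1)
    expect_true(seg$t_onset < seg$t_zero && seg$t_zero < seg$t_end)
    feats <- extract_scalar_features(wf, seg)
    expect_true(all(as.numeric(feats) >= 0))
    expect_lt(feats$time_to_zero_s, feats$total_duration_s)
  }
})

test_that("scalar features of the half-sine twitch match their closed forms", {
  A <- 0.02
  D <- 0.2
  wf <- half_sine_waveform(A, D)
  seg <- segment_twitch(wf, 0)
  f <- extract_scalar_features(wf, seg)
  expect_equal(f$peak_velocity_mps, A, tolerance = 1e-3)
  expect_lt(abs(f$time_to_zero_s - D / 2), 2e-3)
  expect_lt(abs(f$total_duration_s - D), 2e-3)
  expect_equal(f$peak_vti_m, A * D / pi, tolerance = 1e-2)

  # all-zero waveform under a forced segmentation -> all-zero features
  zero <- new_velocity_waveform(rep(0, 600), wf$times, 1000)
  forced <- structure(list(t_onset = 0.05, t_zero = 0.15, t_end = 0.25),
                      class = "twitch_segmentation")
  fz <- extract_scalar_features(zero, forced)
  expect_equal(as.numeric(fz), c(0, 0.1, 0.2, 0))
})

test_that("features are invariant under waveform polarity", {
  wf <- half_sine_waveform()
  neg <- new_velocity_waveform(-wf$values, wf$times, wf$rate)
  f1 <- extract_scalar_features(wf, segment_twitch(wf, 0))
  f2 <- extract_scalar_features(neg, segment_twitch(neg, 0))
  expect_equal(f1, f2)
})

test_that("peak strain rate recovers a constant spatial gradient and zeroes on uniform fields", {
  params <- acquisition_params(n_pulses = 10)
  # smoothing window geometry: 100 samples at 40 MHz, c = 1540 m/s
  expect_equal(round(1.925e-3 / depth_step(params)), 100)

  times <- seq(5e-4, 0.3, by = 1e-3)
  g <- sin(pi * pmin(times / 0.3, 1))
  d <- depth_axis(params)
  k <- 2
  v <- outer(k * (d - mean(d)) + 0.01, g)
  fld <- velocity_field(v, times, 1000, params)
  seg <- structure(list(t_onset = 0.01, t_zero = 0.29, t_end = 0.3),
                   class = "twitch_segmentation")
  expect_equal(peak_strain_rate(fld, seg), k, tolerance = 0.01)

  uni <- velocity_field(matrix(0.01, length(d), length(times)), times, 1000,
                        params)
  expect_equal(peak_strain_rate(uni, seg), 0)

  thin <- acquisition_params(gate_upper = 20, gate_lower = 21, n_pulses = 10)
  vthin <- velocity_field(matrix(0.01, n_depth_samples(thin), 5),
                          1:5 / 10, 1000, thin)
  seg2 <- structure(list(t_onset = 0.1, t_zero = 0.4, t_end = 0.5),
                    class = "twitch_segmentation")
  expect_error(peak_strain_rate(vthin, seg2),
               class = "twitchtdi_invalid_argument")
})

test_that("measured features track the kinematic oracle through the full RF chain", {
  kin <- default_kin()
  params <- acquisition_params(n_pulses = 6000)

  oracle_wf <- expected_gate_waveform(kin, params, 0.6)
  oracle_seg <- segment_twitch(oracle_wf, 0.1)
  oracle_f <- extract_scalar_features(oracle_wf, oracle_seg)
  oracle_fld <- expected_velocity_field(kin, params,
                                        seq(5e-4, 0.5995, by = 1e-3))
  oracle_sr <- peak_strain_rate(oracle_fld, oracle_seg)

  run_one <- function(seed, snr, noise_seed = NULL) {
    ph <- build_phantom(params, density = 15, seed = seed)
    rf <- suppressWarnings(simulate_rf_twitch(ph, kin, params, snr_db = snr,
                                              noise_seed = noise_seed))
    analyze_twitch(rf, stim_time = 0.1)
  }

  # noiseless: median over three phantoms within 2% (amplitudes) / 5 ms (times)
  noiseless <- dplyr::bind_rows(lapply(c(3, 7, 11), run_one, snr = Inf))
  med <- apply(noiseless, 2, stats::median)
  expect_equal(unname(med["peak_velocity_mps"]), oracle_f$peak_velocity_mps,
               tolerance = 0.02)
  expect_equal(unname(med["peak_vti_m"]), oracle_f$peak_vti_m,
               tolerance = 0.02)
  expect_equal(unname(med["peak_strain_rate_per_s"]), oracle_sr,
               tolerance = 0.02)
  expect_lt(abs(med["time_to_zero_s"] - oracle_f$time_to_zero_s), 5e-3)
  expect_lt(abs(med["total_duration_s"] - oracle_f$total_duration_s), 5e-3)

  # 30 dB SNR single realization within 10% / 10 ms
  noisy <- run_one(3, snr = 30, noise_seed = 5)
  expect_equal(noisy$peak_velocity_mps, oracle_f$peak_velocity_mps,
               tolerance = 0.1)
  expect_equal(noisy$peak_vti_m, oracle_f$peak_vti_m, tolerance = 0.1)
  expect_equal(noisy$peak_strain_rate_per_s, oracle_sr, tolerance = 0.1)
  expect_lt(abs(noisy$time_to_zero_s - oracle_f$time_to_zero_s), 1e-2)
  expect_lt(abs(noisy$total_duration_s - oracle_f$total_duration_s), 1e-2)
})
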