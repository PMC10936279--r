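#' RF scanline series container
#'
#' Holds a simulated (or loaded) beamformed RF scanline series: a matrix of
#' echo samples with fast-time (depth) samples in rows and Doppler pulses in
#' columns, plus the acquisition parameters. Fast-time sample `n` (1-based)
#' maps to depth `gate_upper + (n - 1) * depth_step`.
#'
#' @param samples Numeric matrix, `n_depth_samples(params)` rows.
#' @param params An [acquisition_params()] object.
#' @param start_time Time of the first pulse, s.
#' @return An object of class `rf_series`.
#' @export
rf_series <- function(samples, params, start_time = 0) {
  stopifnot(is.matrix(samples), inherits(params, "acquisition_params"))
  if (nrow(samples) != n_depth_samples(params)) {
    abort(sprintf(
      "RF matrix has %d depth samples but the gate spans %d.",
      nrow(samples), n_depth_samples(params)),
      class = "twitchtdi_invalid_argument")
  }
  structure(
    list(samples = samples, params = params, start_time = start_time,
         pulse_times = start_time + (seq_len(ncol(samples)) - 1) / params$prf),
    class = "rf_series"
  )
}

#' @export
print.rf_series <- function(x, ...) {
  cat(sprintf("<rf_series> %d depth samples x %d pulses (%.3g s at %.4g kHz PRF)\n",
              nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / x$params$prf, x$params$prf / 1e3))
  invisible(x)
}

# sigma_t of the Gaussian pulse envelope for a -6 dB fractional bandwidth
pulse_sigma_t <- function(center_frequency, fractional_bandwidth = 0.6) {
  bw <- fractional_bandwidth * center_frequency
  sigma_f <- bw / (2 * sqrt(2 * log(2)))   # -6 dB two-sided width in amplitude
  1 / (2 * pi * sigma_f)
}

#' Simulate an RF scanline series under a prescribed displacement
#'
#' Core echo model: each pulse's scanline is the sum over scatterers of
#' `reflectivity * exp(-(t - tau)^2 / (2 sigma^2)) * cos(2 pi F_c (t - tau))`
#' with two-way delay `tau = 2 (depth - displacement) / c`, sampled at
#' `sample_rate` over the gate. Between pulses scatterers move per the
#' displacement function (positive displacement = toward the transducer).
#' Optional additive white Gaussian noise at a prescribed RF SNR.
#'
#' @param phantom A [build_phantom()] phantom.
#' @param params An [acquisition_params()] object.
#' @param displacement_fn `function(depth_m, time_s)` returning the axial
#'   displacement toward the probe (m) of tissue initially at `depth_m`;
#'   vectorised over both arguments (equal lengths).
#' @param start_time Time of the first pulse, s.
#' @param snr_db RF signal-to-noise ratio in dB; `Inf` for noiseless.
#' @param fractional_bandwidth -6 dB fractional bandwidth of the Gaussian
#'   pulse envelope.
#' @param noise_seed Optional integer seed for the noise draw only.
#' @return An [rf_series()].
#' @export
simulate_rf_series <- function(phantom, params, displacement_fn,
                               start_time = 0, snr_db = 30,
                               fractional_bandwidth = 0.6,
                               noise_seed = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(params, "acquisition_params"))
  n_samp <- n_depth_samples(params)
  pulse_times <- start_time + (seq_len(params$n_pulses) - 1) / params$prf
  depths_m <- phantom$scatterer_depths / 1000
  n_scat <- length(depths_m)

  # displacement of every scatterer at every pulse time (m, toward probe)
  disp <- matrix(
    displacement_fn(rep(depths_m, times = params$n_pulses),
                    rep(pulse_times, each = n_scat)),
    nrow = n_scat
  )

  # drop scatterers that ever leave the phantom margin
  lo_m <- (params$gate_upper - phantom$margin) / 1000
  hi_m <- (params$gate_lower + phantom$margin) / 1000
  pos <- depths_m - disp
  out <- apply(pos < lo_m | pos > hi_m, 1, any)
  if (any(out)) {
    warn(sprintf("%d scatterer(s) left the gate margin and were dropped.",
                 sum(out)))
    keep <- !out
    depths_m <- depths_m[keep]
    disp <- disp[keep, , drop = FALSE]
    refl <- phantom$reflectivities[keep]
  } else {
    refl <- phantom$reflectivities
  }

  sigma_t <- pulse_sigma_t(params$center_frequency, fractional_bandwidth)
  t0 <- 2 * params$gate_upper / 1000 / params$speed_of_sound
  rf <- rf_sim_kernel(depths_m, refl, disp, n_samp,
                      params$sample_rate, params$center_frequency,
                      params$speed_of_sound, t0, sigma_t, 4)

  if (is.finite(snr_db)) {
    sig_rms <- sqrt(mean(rf^2))
    noise_sd <- sig_rms / 10^(snr_db / 20)
    noise <- if (is.null(noise_seed)) {
      rnorm(length(rf), sd = noise_sd)
    } else {
      withr_seed(noise_seed, rnorm(length(rf), sd = noise_sd))
    }
    rf <- rf + noise
  }
  rf_series(rf, params, start_time = start_time)
}

#' Simulate the RF acquisition of one muscle twitch
#'
#' Convenience wrapper around [simulate_rf_series()] using the twitch
#' kinematics of [twitch_kinematics()]: tissue initially at depth `d` moves
#' by `twitch_motion(kin, t, depth = d)` with the linear depth dependence
#' referenced to the gate center.
#'
#' @inheritParams simulate_rf_series
#' @param kin A [twitch_kinematics()] object.
#' @return An [rf_series()].
#' @examples
#' params <- acquisition_params(gate_upper = 20, gate_lower = 24, n_pulses = 500)
#' ph <- build_phantom(params, density = 6, seed = 2)
#' rf <- simulate_rf_twitch(ph, twitch_kinematics(onset_time = 0.01), params,
#'                          snr_db = Inf)
#' @export
simulate_rf_twitch <- function(phantom, kin, params, start_time = 0,
                               snr_db = 30, noise_seed = NULL) {
  stopifnot(inherits(kin, "twitch_kinematics"))
  window <- params$n_pulses / params$prf
  if (start_time + window < kin$onset_time + kin$total_duration) {
    warn("pulse sequence does not cover the full twitch window.")
  }
  d_center <- mean(c(params$gate_upper, params$gate_lower)) / 1000
  fn <- function(depth_m, time_s) {
    twitch_motion(kin, time_s, depth = depth_m, depth_center = d_center)
  }
  simulate_rf_series(phantom, params, fn, start_time = start_time,
                     snr_db = snr_db, noise_seed = noise_seed)
}
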