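# shared fixtures: small acquisition geometries and canonical twitches

small_params <- function(n_pulses = 300, gate_upper = 20, gate_lower = 26) {
  acquisition_params(gate_upper = gate_upper, gate_lower = gate_lower,
                     n_pulses = n_pulses)
}

default_kin <- function() {
  twitch_kinematics(onset_time = 0.15, expansion_duration = 0.1,
                    total_duration = 0.25, peak_velocity_amplitude = 0.02,
                    depth_gradient = 1.5)
}

# half-sine test waveform: v = A sin(2 pi t / D) on [0, D], zero-padded
half_sine_waveform <- function(A = 0.02, D = 0.2, duration = 0.6,
                               rate = 1000) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  v <- ifelse(t <= D, A * sin(2 * pi * t / D), 0)
  new_velocity_waveform(v, t, rate)
}

# uniform-motion RF series (constant velocity toward the probe); sustained
# drift inevitably carries a few margin-grazing scatterers out, so the drop
# warning is silenced here
uniform_rf <- function(v, params, seed, snr_db = Inf, density = 15) {
  ph <- build_phantom(params, density = density, seed = seed)
  suppressWarnings(
    simulate_rf_series(ph, params, function(d, t) v * t, snr_db = snr_db))
}

feature_names5 <- c("peak_velocity_mps", "time_to_zero_s",
                    "total_duration_s", "peak_vti_m",
                    "peak_strain_rate_per_s")
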