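#' Closed-form prediction of the Doppler-measured twitch velocity
#'
#' The velocity estimator reports the tissue velocity at *fixed depths*
#' (an Eulerian measurement), while [twitch_kinematics()] prescribes the
#' motion of *material points* (Lagrangian). When the peak velocity varies
#' across depth (`depth_gradient != 0`), tissue from neighbouring depths is
#' advected through each pixel, so the measured velocity at pixel depth `d`
#' is that of the material point `d0` currently located there, found from
#' `d0 - x(d0, t) = d`. These functions evaluate that prediction exactly
#' (by fixed-point iteration on `d0`) on the acquisition's pixel grid,
#' giving an independent kinematic oracle for the full simulate-estimate
#' chain: `expected_velocity_field()` the per-pixel field, and
#' `expected_gate_waveform()` its unweighted gate average.
#'
#' @param kin A [twitch_kinematics()] object.
#' @param params An [acquisition_params()] object (pixel grid and gate).
#' @param times Time points, s.
#' @return `expected_velocity_field()`: a [velocity_field()];
#'   `expected_gate_waveform()`: a [new_velocity_waveform()].
#' @export
expected_velocity_field <- function(kin, params, times) {
  d <- depth_axis(params)
  d_center <- mean(c(params$gate_upper, params$gate_lower)) / 1000
  v <- matrix(0, nrow = length(d), ncol = length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    d0 <- d
    for (it in 1:3) {
      d0 <- d + twitch_motion(kin, rep(t, length(d0)), depth = d0,
                              depth_center = d_center)
    }
    v[, j] <- twitch_velocity(kin, rep(t, length(d0)), depth = d0,
                              depth_center = d_center)
  }
  velocity_field(v, times, rate = 1 / mean(diff(times)), params = params)
}

#' @rdname expected_velocity_field
#' @param duration Record duration, s.
#' @param rate Sampling rate, Hz.
#' @export
expected_gate_waveform <- function(kin, params, duration, rate = 1000) {
  times <- seq(0, duration - 1 / rate, by = 1 / rate) + 0.5 / rate
  fld <- expected_velocity_field(kin, params, times)
  average_over_gate(fld)
}
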