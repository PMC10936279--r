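#' Isometric twitch kinematics
#'
#' Parametric model of the tissue velocity of one electrically evoked
#' isometric twitch, as seen along the Doppler scan line. The twitch has an
#' active expansion phase (net motion toward the transducer, positive
#' velocity) followed by a passive return phase of opposite sign, with
#' exactly one velocity zero-crossing in between. Displacement returns to
#' zero at the end of the twitch (isometric closure).
#'
#' The velocity at the gate center is two half-sine lobes,
#' \deqn{v(t) = V_p \sin(\pi (t - t_0)/T_e)} on the expansion interval
#' `[onset, onset + expansion_duration]` and
#' \deqn{v(t) = -V_r \sin(\pi (t - t_0 - T_e)/(D - T_e))} on the return
#' interval, with the return amplitude `V_r = V_p * T_e / (D - T_e)` chosen
#' so that the displacement integrates back to zero. This is the Hann-squared
#' displacement bump with a piecewise-linear time warp placing the velocity
#' zero-crossing at `onset + expansion_duration`.
#'
#' Across the gate, the peak velocity varies linearly with depth:
#' `V_p(d) = peak_velocity_amplitude + depth_gradient * (d - d_center)`,
#' giving a constant, known spatial velocity gradient whose magnitude is the
#' ground-truth peak strain rate.
#'
#' @param onset_time Twitch onset (time point 1) in s.
#' @param expansion_duration Ground-truth time-to-zero velocity in s
#'   (time point 2 minus time point 1).
#' @param total_duration Ground-truth total twitch duration in s
#'   (time point 3 minus time point 1). Must exceed `expansion_duration`.
#' @param peak_velocity_amplitude Peak expansion velocity at gate center, m/s.
#' @param depth_gradient Linear slope of peak velocity across depth, 1/s
#'   (i.e. (m/s)/m); the ground-truth peak strain rate magnitude.
#'
#' @return An object of class `twitch_kinematics`.
#' @examples
#' kin <- twitch_kinematics()
#' twitch_velocity(kin, time = kin$onset_time + kin$expansion_duration / 2)
#' @export
twitch_kinematics <- function(onset_time = 0.15,
                              expansion_duration = 0.1,
                              total_duration = 0.25,
                              peak_velocity_amplitude = 0.02,
                              depth_gradient = 1.5) {
  stopifnot(onset_time >= 0, expansion_duration > 0,
            total_duration > expansion_duration,
            peak_velocity_amplitude >= 0)
  structure(
    list(onset_time = onset_time,
         expansion_duration = expansion_duration,
         total_duration = total_duration,
         peak_velocity_amplitude = peak_velocity_amplitude,
         depth_gradient = depth_gradient),
    class = "twitch_kinematics"
  )
}

peak_velocity_at_depth <- function(kin, depth, depth_center) {
  if (is.null(depth)) return(kin$peak_velocity_amplitude)
  kin$peak_velocity_amplitude + kin$depth_gradient * (depth - depth_center)
}

#' Twitch velocity and displacement at a depth and time
#'
#' `twitch_velocity()` evaluates the prescribed tissue velocity (m/s,
#' positive toward the transducer) and `twitch_motion()` its running time
#' integral, the axial displacement toward the transducer (m). Both are zero
#' before onset; displacement is zero again at `onset_time + total_duration`.
#'
#' @param kin A [twitch_kinematics()] object.
#' @param time Time(s) in s (vectorised).
#' @param depth Depth in m at which to evaluate (scalar or vector recycled
#'   against `time`), or `NULL` for the gate-center amplitude.
#' @param depth_center Gate-center depth in m used as the reference for the
#'   linear depth dependence.
#' @return Numeric vector of velocities (m/s) or displacements (m).
#' @export
twitch_velocity <- function(kin, time, depth = NULL, depth_center = 0) {
  vp <- rep_len(peak_velocity_at_depth(kin, depth, depth_center), length(time))
  te <- kin$expansion_duration
  d  <- kin$total_duration
  vr <- vp * te / (d - te)
  s  <- time - kin$onset_time
  v  <- numeric(length(time))
  exp_phase <- s >= 0 & s <= te
  ret_phase <- s > te & s <= d
  v[exp_phase] <- vp[exp_phase] * sin(pi * s[exp_phase] / te)
  v[ret_phase] <- -vr[ret_phase] * sin(pi * (s[ret_phase] - te) / (d - te))
  v
}

#' @rdname twitch_velocity
#' @export
twitch_motion <- function(kin, time, depth = NULL, depth_center = 0) {
  vp <- rep_len(peak_velocity_at_depth(kin, depth, depth_center), length(time))
  te <- kin$expansion_duration
  d  <- kin$total_duration
  vr <- vp * te / (d - te)
  peak_disp <- 2 * vp * te / pi
  s <- time - kin$onset_time
  x <- numeric(length(time))
  exp_phase <- s >= 0 & s <= te
  ret_phase <- s > te & s <= d
  x[exp_phase] <- vp[exp_phase] * te / pi * (1 - cos(pi * s[exp_phase] / te))
  x[ret_phase] <- peak_disp[ret_phase] -
    vr[ret_phase] * (d - te) / pi *
    (1 - cos(pi * (s[ret_phase] - te) / (d - te)))
  x
}

#' Ground-truth waveform features of a twitch
#'
#' Closed-form values of the five waveform features for a noiseless twitch
#' generated by [twitch_kinematics()]: peak velocity `V_p`, time-to-zero
#' `T_e`, total duration `D`, peak velocity-time integral `2 V_p T_e / pi`
#' (displacement accumulated over the expansion phase), and peak strain rate
#' `|depth_gradient|`.
#'
#' @param kin A [twitch_kinematics()] object.
#' @return A one-row tibble with columns `peak_velocity_mps`,
#'   `time_to_zero_s`, `total_duration_s`, `peak_vti_m`,
#'   `peak_strain_rate_per_s`.
#' @export
true_twitch_features <- function(kin) {
  tibble(
    peak_velocity_mps = kin$peak_velocity_amplitude,
    time_to_zero_s = kin$expansion_duration,
    total_duration_s = kin$total_duration,
    peak_vti_m = 2 * kin$peak_velocity_amplitude * kin$expansion_duration / pi,
    peak_strain_rate_per_s = abs(kin$depth_gradient)
  )
}

#' Noiseless analytic velocity waveform on a sampling grid
#'
#' Evaluates the prescribed gate-center twitch velocity on a regular time
#' grid, returning a [velocity_waveform] — the ground truth against which the
#' Doppler-estimated waveform can be compared.
#'
#' @inheritParams twitch_velocity
#' @param duration Record duration in s.
#' @param rate Sampling rate in Hz (default 1 kHz, the analysis rate).
#' @return A `velocity_waveform` object.
#' @export
analytic_waveform <- function(kin, duration, rate = 1000) {
  times <- seq(0, duration - 1 / rate, by = 1 / rate)
  new_velocity_waveform(twitch_velocity(kin, times), times, rate)
}
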