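#' Pulsed-Doppler acquisition parameters
#'
#' Bundles the acquisition constants of a single-scanline pulsed-wave tissue
#' Doppler recording: transducer center frequency, RF sampling rate, pulse
#' repetition frequency (PRF), assumed speed of sound, and the depth interval
#' of the Doppler gate over which velocities are estimated and averaged.
#'
#' @param center_frequency Transducer center frequency F_c in Hz.
#' @param sample_rate RF (fast-time) sampling rate in Hz; must exceed
#'   `2 * center_frequency`.
#' @param prf Pulse repetition frequency in Hz. The inter-pulse period is
#'   `T = 1 / prf`.
#' @param speed_of_sound Assumed speed of sound c in m/s (soft-tissue
#'   convention 1540 m/s).
#' @param gate_upper,gate_lower Upper (shallow) and lower (deep) boundary of
#'   the Doppler gate, in mm depth. `gate_upper < gate_lower`.
#' @param n_pulses Number of Doppler pulses in the recording.
#'
#' @return An object of class `acquisition_params`.
#' @examples
#' p <- acquisition_params()
#' nyquist_velocity(p)
#' @export
acquisition_params <- function(center_frequency = 6.66e6,
                               sample_rate = 40e6,
                               prf = 10e3,
                               speed_of_sound = 1540,
                               gate_upper = 15,
                               gate_lower = 35,
                               n_pulses = 6000) {
  stopifnot(is.numeric(center_frequency), center_frequency > 0,
            is.numeric(sample_rate), is.numeric(prf), prf > 0,
            is.numeric(speed_of_sound), speed_of_sound > 0,
            is.numeric(n_pulses), n_pulses >= 1)
  if (sample_rate <= 2 * center_frequency) {
    abort("`sample_rate` must exceed twice `center_frequency`.",
          class = "twitchtdi_invalid_argument")
  }
  if (!(gate_upper < gate_lower)) {
    abort("`gate_upper` must be strictly shallower than `gate_lower` (mm).",
          class = "twitchtdi_invalid_argument")
  }
  structure(
    list(center_frequency = center_frequency,
         sample_rate = sample_rate,
         prf = prf,
         speed_of_sound = speed_of_sound,
         gate_upper = gate_upper,
         gate_lower = gate_lower,
         n_pulses = as.integer(n_pulses)),
    class = "acquisition_params"
  )
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("<acquisition_params>\n")
  cat(sprintf("  F_c %.3g MHz, fs %.3g MHz, PRF %.4g kHz, c %g m/s\n",
              x$center_frequency / 1e6, x$sample_rate / 1e6, x$prf / 1e3,
              x$speed_of_sound))
  cat(sprintf("  gate [%g, %g] mm (%d depth samples), %d pulses (%.3g s)\n",
              x$gate_upper, x$gate_lower, n_depth_samples(x), x$n_pulses,
              x$n_pulses / x$prf))
  invisible(x)
}

#' Derived acquisition geometry
#'
#' `depth_step()` is the axial extent of one RF sample, `c / (2 * sample_rate)`
#' in m. `n_depth_samples()` is the number of RF samples spanning the gate.
#' `depth_axis()` returns the depth (m) of each RF sample, starting at the
#' upper gate boundary. `nyquist_velocity()` is the largest unambiguous
#' Doppler velocity `c * prf / (4 * F_c)` in m/s.
#'
#' @param params An [acquisition_params()] object.
#' @return A numeric scalar (or vector for `depth_axis()`).
#' @export
depth_step <- function(params) {
  params$speed_of_sound / (2 * params$sample_rate)
}

#' @rdname depth_step
#' @export
n_depth_samples <- function(params) {
  span_m <- (params$gate_lower - params$gate_upper) / 1000
  as.integer(round(span_m * 2 / params$speed_of_sound * params$sample_rate))
}

#' @rdname depth_step
#' @export
depth_axis <- function(params) {
  params$gate_upper / 1000 + (seq_len(n_depth_samples(params)) - 1) * depth_step(params)
}

#' @rdname depth_step
#' @export
nyquist_velocity <- function(params) {
  params$speed_of_sound * params$prf / (4 * params$center_frequency)
}
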