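#' Extract the scalar waveform features of one twitch
#'
#' Given a segmented twitch velocity waveform, computes four of the five
#' fatigue-sensitive features:
#'
#' * `peak_velocity_mps` — maximum absolute velocity during the expansion
#'   phase, i.e. on `[t_onset, t_zero]`.
#' * `time_to_zero_s` — `t_zero - t_onset`.
#' * `total_duration_s` — `t_end - t_onset`.
#' * `peak_vti_m` — the peak velocity-time integral: absolute value of the
#'   cumulative trapezoidal integral of the velocity from onset, evaluated
#'   at the zero-crossing (where the running integral is extremal). The
#'   absolute value makes the feature polarity-invariant.
#'
#' The fifth feature, peak strain rate, needs the depth-resolved field; see
#' [peak_strain_rate()].
#'
#' @param waveform A [new_velocity_waveform()].
#' @param seg A [segment_twitch()] result.
#' @return A one-row tibble with the four features.
#' @export
extract_scalar_features <- function(waveform, seg) {
  stopifnot(inherits(waveform, "velocity_waveform"),
            inherits(seg, "twitch_segmentation"))
  times <- waveform$times
  if (seg$t_onset < times[1] || seg$t_end > times[length(times)] + 1e-9) {
    abort("segmentation lies outside the waveform.",
          class = "twitchtdi_invalid_argument")
  }
  in_exp <- times >= seg$t_onset & times <= seg$t_zero
  peak_velocity <- max(abs(waveform$values[in_exp]))

  idx <- which(times >= seg$t_onset & times <= seg$t_zero)
  vti <- if (length(idx) >= 2) {
    ci <- pracma::cumtrapz(times[idx], waveform$values[idx])
    abs(ci[length(ci)])
  } else 0

  tibble(
    peak_velocity_mps = peak_velocity,
    time_to_zero_s = seg$t_zero - seg$t_onset,
    total_duration_s = seg$t_end - seg$t_onset,
    peak_vti_m = as.numeric(vti)
  )
}

#' Peak tissue strain rate over the expansion phase
#'
#' Approximates the peak tissue strain rate from a velocity field: each time
#' column is smoothed along depth with a moving average of physical length
#' `smooth_len` (1.925 mm, i.e. 100 samples at 40 MHz with c = 1540 m/s),
#' the spatial velocity gradient along depth is computed by central/forward
#' differences, averaged over the gate, and the maximum absolute average
#' gradient over `[t_onset, t_zero]` is returned.
#'
#' @param field A [velocity_field()] covering the segmentation interval.
#' @param seg A [segment_twitch()] result.
#' @param smooth_len Axial smoothing length in m (default 1.925e-3).
#' @return Peak strain rate, 1/s.
#' @export
peak_strain_rate <- function(field, seg, smooth_len = 1.925e-3) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(seg, "twitch_segmentation"))
  dstep <- depth_step(field$params)
  w <- max(1L, as.integer(round(smooth_len / dstep)))
  if (nrow(field$velocities) <= w) {
    abort("gate is thinner than the smoothing window.",
          class = "twitchtdi_invalid_argument")
  }
  keep <- field$times >= seg$t_onset & field$times <= seg$t_zero
  if (!any(keep)) {
    abort("field does not cover the segmentation interval.",
          class = "twitchtdi_invalid_argument")
  }
  v <- field$velocities[, keep, drop = FALSE]
  if (w > 1) {
    v <- stats::filter(v, rep(1 / w, w), sides = 2)
    v <- v[stats::complete.cases(v), , drop = FALSE]
  }
  grad <- diff(v) / dstep
  avg_grad <- colMeans(grad)
  max(abs(avg_grad))
}

#' Analyze one twitch recording end to end
#'
#' Runs the full per-twitch analysis chain on an RF recording: analytic
#' signal, lag-one autocorrelation velocity field, 1-kHz downsampling,
#' depth averaging, three-point segmentation, and the five waveform
#' features.
#'
#' @param rf An [rf_series()].
#' @param stim_time Stimulus time, s.
#' @param target_rate Analysis rate, Hz.
#' @param ... Passed to [segment_twitch()].
#' @return A one-row tibble with `t_onset_s`, `t_zero_s`, `t_end_s` and the
#'   five features.
#' @export
analyze_twitch <- function(rf, stim_time, target_rate = 1000, ...) {
  field <- estimate_velocity_field(to_analytic(rf))
  field_1k <- downsample_velocity(field, target_rate)
  wf <- average_over_gate(field_1k)
  seg <- segment_twitch(wf, stim_time, ...)
  feats <- extract_scalar_features(wf, seg)
  dplyr::bind_cols(
    tibble(t_onset_s = seg$t_onset, t_zero_s = seg$t_zero,
           t_end_s = seg$t_end),
    feats,
    tibble(peak_strain_rate_per_s = peak_strain_rate(field_1k, seg))
  )
}

#' Segment and featurize a bare waveform (no depth-resolved field)
#'
#' Used for waveform-level synthetic studies: segmentation plus the four
#' scalar features; the strain-rate column is filled with `NA` unless
#' supplied.
#' @inheritParams analyze_twitch
#' @param waveform A [new_velocity_waveform()].
#' @param strain_rate Optional known strain rate to carry through, 1/s.
#' @return A one-row tibble matching [analyze_twitch()]'s columns.
#' @export
analyze_waveform <- function(waveform, stim_time, strain_rate = NA_real_, ...) {
  seg <- segment_twitch(waveform, stim_time, ...)
  feats <- extract_scalar_features(waveform, seg)
  dplyr::bind_cols(
    tibble(t_onset_s = seg$t_onset, t_zero_s = seg$t_zero,
           t_end_s = seg$t_end),
    feats,
    tibble(peak_strain_rate_per_s = strain_rate)
  )
}
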