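#' Analytic (IQ) signal of an RF series
#'
#' Converts each pulse's RF scanline to its complex analytic signal
#' (in-phase and quadrature components) along the fast-time/depth axis via
#' the FFT half-spectrum construction of the Hilbert transform: positive
#' frequencies doubled, negative frequencies zeroed. The real part of the
#' result equals the original RF.
#'
#' @param rf An [rf_series()].
#' @return An object of class `iq_series`: complex matrix `samples` of the
#'   same shape plus the acquisition parameters.
#' @export
to_analytic <- function(rf) {
  stopifnot(inherits(rf, "rf_series"))
  m <- rf$samples
  if (!all(is.finite(m))) {
    abort("RF samples contain non-finite values.",
          class = "twitchtdi_invalid_argument")
  }
  n <- nrow(m)
  if (n < 8) {
    abort("need at least 8 depth samples for the analytic signal.",
          class = "twitchtdi_invalid_argument")
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- mvfft(mvfft(m) * h, inverse = TRUE) / n
  structure(
    list(samples = z, params = rf$params, start_time = rf$start_time,
         pulse_times = rf$pulse_times),
    class = "iq_series"
  )
}

#' Velocity field container
#'
#' Per-depth, per-time tissue velocity estimates over the Doppler gate.
#' Row `i` is depth `gate_upper + (i - 1) * depth_step`; columns are time
#' points at `rate` Hz starting at `times[1]`.
#'
#' @param velocities Numeric matrix (depth sample x time).
#' @param times Time of each column, s.
#' @param rate Temporal rate of the columns, Hz.
#' @param params The originating [acquisition_params()].
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(velocities, times, rate, params) {
  stopifnot(is.matrix(velocities), length(times) == ncol(velocities))
  structure(
    list(velocities = velocities, times = times, rate = rate, params = params),
    class = "velocity_field"
  )
}

#' Estimate the tissue velocity field by lag-one phase autocorrelation
#'
#' For every depth sample and pulse pair, the phase of the lag-one
#' autocorrelation `z(d, t + T) * Conj(z(d, t))` of the analytic signal
#' gives the pulse-to-pulse phase shift `dphi`, converted to velocity by
#' \deqn{v(t, d) = c \, \Delta\phi(t, d) / (4 \pi F_c T),}
#' where `T = 1/prf`. Motion toward the transducer (decreasing depth) yields
#' positive velocity. Before the phase is taken, the lag-one products are
#' averaged over a short sliding ensemble in slow time and over a small
#' axial window (about one pulse length), the usual variance-reduction
#' practice for phase autocorrelation: dark speckle pixels carry almost no
#' phase information of their own and borrow it from their axial
#' neighbourhood. Estimates are bounded by the Nyquist velocity
#' `c * prf / (4 F_c)`; faster motion wraps.
#'
#' @param iq An `iq_series` from [to_analytic()].
#' @param ensemble Number of consecutive lag-one products averaged (trailing
#'   window; shorter at the record start).
#' @param axial_ensemble Axial (depth) smoothing window on the lag products,
#'   in samples; default 9 (about one pulse length at 40 MHz).
#' @return A [velocity_field()] at the pulse rate, with the first column
#'   assigned to `start_time + T/2`.
#' @export
estimate_velocity_field <- function(iq, ensemble = 4, axial_ensemble = 9) {
  stopifnot(inherits(iq, "iq_series"))
  z <- iq$samples
  p <- iq$params
  n_pulses <- ncol(z)
  if (n_pulses < 2) {
    abort("need at least 2 pulses to estimate velocity.",
          class = "twitchtdi_invalid_argument")
  }
  r <- z[, 2:n_pulses, drop = FALSE] * Conj(z[, 1:(n_pulses - 1), drop = FALSE])
  m <- ncol(r)
  ens <- max(1L, min(as.integer(ensemble), m))
  acc <- r
  if (ens > 1) {
    for (k in seq_len(ens - 1)) {
      idx <- (k + 1):m
      acc[, idx] <- acc[, idx] + r[, idx - k, drop = FALSE]
    }
    # leading columns averaged over fewer products; phase is count-invariant
  }
  ax <- max(1L, as.integer(axial_ensemble))
  if (ax > 1 && nrow(acc) > ax) {
    kern <- rep(1, ax)
    re <- stats::filter(Re(acc), kern, sides = 2)
    im <- stats::filter(Im(acc), kern, sides = 2)
    sm <- complex(real = re, imaginary = im)
    dim(sm) <- dim(acc)
    edge <- is.na(Re(sm))
    sm[edge] <- acc[edge]
    acc <- sm
  }
  dphi <- Arg(acc)
  t_period <- 1 / p$prf
  v <- p$speed_of_sound * dphi / (4 * pi * p$center_frequency * t_period)
  times <- iq$start_time + (seq_len(m) - 0.5) * t_period
  velocity_field(v, times, rate = p$prf, params = p)
}

#' Downsample a velocity field in time by block averaging
#'
#' Averages velocity columns into consecutive output intervals of
#' `1/target_rate` s (anti-aliasing low-pass by block mean, emphasising the
#' low tissue velocities of interest). A final partial block is dropped.
#'
#' @param field A [velocity_field()].
#' @param target_rate Output rate, Hz (default 1 kHz). Must not exceed the
#'   field's rate.
#' @return A [velocity_field()] at `target_rate`, columns timed at block
#'   centers.
#' @export
downsample_velocity <- function(field, target_rate = 1000) {
  stopifnot(inherits(field, "velocity_field"))
  if (target_rate > field$rate) {
    abort("`target_rate` exceeds the field's rate.",
          class = "twitchtdi_invalid_argument")
  }
  t0 <- field$times[1]
  # small epsilon guards against floor() flipping at exact bin boundaries
  bin <- floor((field$times - t0) * target_rate + 1e-9)
  per_bin_full <- floor(field$rate / target_rate)
  counts <- tabulate(bin + 1L)
  full <- which(counts >= per_bin_full)
  n_full <- if (length(full)) max(full) else 0L
  if (n_full < 1) {
    abort("record shorter than one output interval.",
          class = "twitchtdi_invalid_argument")
  }
  keep <- bin < n_full
  sums <- rowsum(t(field$velocities[, keep, drop = FALSE]), bin[keep])
  v <- t(sums / counts[seq_len(n_full)])
  dimnames(v) <- NULL
  times <- t0 + (seq_len(n_full) - 0.5) / target_rate
  velocity_field(v, times, rate = target_rate, params = field$params)
}

#' Depth-averaged velocity waveform container
#'
#' The 1-D twitch velocity trace obtained by averaging a velocity field
#' across the Doppler gate, conventionally at 1 kHz.
#'
#' @param values Velocities, m/s.
#' @param times Sample times, s.
#' @param rate Sampling rate, Hz.
#' @return An object of class `velocity_waveform`.
#' @export
new_velocity_waveform <- function(values, times, rate) {
  stopifnot(length(values) == length(times))
  structure(list(values = values, times = times, rate = rate),
            class = "velocity_waveform")
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf("<velocity_waveform> %d samples at %g Hz, t in [%.3g, %.3g] s\n",
              length(x$values), x$rate, min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as_tibble.velocity_waveform <- function(x, ...) {
  tibble(time_s = x$times, velocity_mps = x$values)
}

#' Average a velocity field across the Doppler gate
#'
#' Unweighted mean across all depth samples inside the gate, per time point,
#' producing the 1-D velocity waveform used for twitch segmentation and
#' feature extraction.
#'
#' @param field A [velocity_field()].
#' @return A [new_velocity_waveform()] at the field's rate.
#' @export
average_over_gate <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  if (nrow(field$velocities) < 1) {
    abort("empty gate.", class = "twitchtdi_invalid_argument")
  }
  new_velocity_waveform(colMeans(field$velocities), field$times, field$rate)
}
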