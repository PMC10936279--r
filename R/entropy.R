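#' Sliding-window spectral entropy of a velocity waveform
#'
#' Normalized Shannon entropy of the windowed power spectrum,
#' `-sum(p * log(p)) / log(N_bins)`, where `p` is the Hann-tapered
#' periodogram over the positive-frequency bins (DC excluded) normalized to
#' unit sum. Values near 1 indicate a noise-like (broadband) window, values
#' near 0 a tonal one; windows with zero variance are assigned entropy 0.
#' Used to guide detection of the end of a twitch: once the deterministic
#' twitch motion has died out, the waveform is broadband noise and the
#' entropy rises above the cutoff (conventionally 0.7 with a 164-sample
#' window at 1 kHz).
#'
#' @param waveform A [new_velocity_waveform()] or numeric vector.
#' @param window Window length in samples (default 164).
#' @param step Hop between window starts, in samples (default `window %/% 4`).
#' @return A tibble with `time_s` (window center; sample index for bare
#'   vectors) and `entropy`.
#' @export
spectral_entropy <- function(waveform, window = 164, step = window %/% 4) {
  if (inherits(waveform, "velocity_waveform")) {
    x <- waveform$values
    times <- waveform$times
  } else {
    x <- as.numeric(waveform)
    times <- seq_along(x)
  }
  n <- length(x)
  if (window > n) {
    abort("`window` is longer than the waveform.",
          class = "twitchtdi_invalid_argument")
  }
  stopifnot(window >= 8, step >= 1)
  starts <- seq(1L, n - window + 1L, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))
  n_bins <- floor(window / 2)
  ent <- vapply(starts, function(i) {
    seg <- x[i:(i + window - 1L)]
    if (sd(seg) == 0) return(0)
    spec <- Mod(fft((seg - mean(seg)) * taper))^2
    p <- spec[2:(n_bins + 1L)]
    tot <- sum(p)
    if (tot <= 0) return(0)
    p <- p / tot
    p <- p[p > 0]
    -sum(p * log(p)) / log(n_bins)
  }, numeric(1))
  centers <- times[starts + window %/% 2]
  tibble(time_s = centers, entropy = ent)
}
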