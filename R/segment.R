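#' Segment a twitch velocity waveform into its three time points
#'
#' Automatic version of the three-point annotation of a twitch velocity
#' waveform: (1) twitch onset, (2) the single zero-crossing of tissue
#' velocity between the expansion and return phases, and (3) the end of the
#' twitch when velocity settles back to baseline. Rules:
#'
#' * **Onset** — first time at or after `stim_time` where `|v|` exceeds
#'   `onset_k` times the robust SD (MAD) of the pre-stimulus baseline for at
#'   least `onset_min_ms` consecutive milliseconds.
#' * **Zero-crossing** — first sign change of `v` after the first `|v|` peak
#'   following onset, located by linear interpolation.
#' * **End** — the earlier of (a) the first time after the zero-crossing
#'   where the sliding-window [spectral_entropy()] exceeds `entropy_cutoff`
#'   for at least half a window, and (b) the start of the first run of at
#'   least `quiet_ms` ms with `|v|` at or below the onset threshold (a
#'   below-threshold run reaching the end of the record also counts).
#'
#' Segmentation is invariant to waveform polarity and equivariant under time
#' shifts. If the pre-stimulus baseline is absent or silent, the threshold
#' falls back to `1e-3 * max |v|`.
#'
#' @param waveform A [new_velocity_waveform()].
#' @param stim_time Stimulus time, s; the baseline is everything before it.
#' @param onset_k Threshold multiplier on the baseline robust SD.
#' @param onset_min_ms Minimum supra-threshold run to accept onset, ms.
#' @param quiet_ms Minimum sub-threshold run to declare the twitch over, ms.
#' @param entropy_cutoff Spectral-entropy cutoff for the end rule.
#' @param entropy_window Spectral-entropy window length, samples.
#' @return An object of class `twitch_segmentation` with fields `t_onset`,
#'   `t_zero`, `t_end` (s), satisfying `t_onset < t_zero < t_end`.
#' @export
segment_twitch <- function(waveform, stim_time,
                           onset_k = 3, onset_min_ms = 5, quiet_ms = 20,
                           entropy_cutoff = 0.7, entropy_window = 164) {
  stopifnot(inherits(waveform, "velocity_waveform"))
  v <- waveform$values
  times <- waveform$times
  rate <- waveform$rate
  av <- abs(v)
  if (max(av) == 0) {
    abort("waveform is identically zero: no twitch detected.",
          class = "twitchtdi_no_twitch")
  }

  base <- v[times < stim_time]
  thr <- if (length(base) >= 20) onset_k * mad(base) else 0
  if (thr == 0) thr <- 1e-3 * max(av)

  ## onset: sustained supra-threshold run after the stimulus
  min_run <- max(1L, as.integer(round(onset_min_ms / 1000 * rate)))
  cand <- which(times >= stim_time & av > thr)
  onset_idx <- first_run_start(cand, min_run)
  if (is.na(onset_idx)) {
    abort("no supra-threshold activity after the stimulus: no twitch detected.",
          class = "twitchtdi_no_twitch")
  }

  ## first |v| peak after onset, then first sign change
  peak_idx <- NA_integer_
  for (i in seq(max(onset_idx, 2L), length(v) - 1L)) {
    if (av[i] > thr && av[i] >= av[i - 1L] && av[i] >= av[i + 1L]) {
      peak_idx <- i
      break
    }
  }
  if (is.na(peak_idx)) {
    abort("no velocity peak found after onset.",
          class = "twitchtdi_segmentation_failure")
  }
  zero_idx <- NA_integer_
  s0 <- sign(v[peak_idx])
  for (i in seq(peak_idx + 1L, length(v))) {
    if (sign(v[i]) == -s0) {
      zero_idx <- i
      break
    }
  }
  if (is.na(zero_idx)) {
    abort("velocity never crosses zero after its first peak.",
          class = "twitchtdi_segmentation_failure")
  }
  # linear interpolation of the crossing between zero_idx - 1 and zero_idx
  i1 <- zero_idx - 1L
  t_zero <- times[i1] +
    (times[zero_idx] - times[i1]) * v[i1] / (v[i1] - v[zero_idx])

  ## end rule (a): sustained high spectral entropy after the zero-crossing
  t_end_entropy <- Inf
  if (length(v) >= entropy_window) {
    ent <- spectral_entropy(waveform, window = entropy_window)
    step <- entropy_window %/% 4
    need <- max(1L, as.integer(ceiling((entropy_window / 2) / step)))
    hi <- which(ent$time_s > t_zero & ent$entropy > entropy_cutoff)
    run <- first_run_start_spaced(hi, need)
    if (!is.na(run)) t_end_entropy <- ent$time_s[run]
  }

  ## end rule (b): |v| back at or below the onset threshold for quiet_ms
  quiet_run <- max(1L, as.integer(round(quiet_ms / 1000 * rate)))
  t_end_quiet <- Inf
  qi <- which(times > t_zero & av <= thr)
  if (length(qi)) {
    breaks <- c(0L, which(diff(qi) != 1L), length(qi))
    for (k in seq_len(length(breaks) - 1L)) {
      run <- qi[(breaks[k] + 1L):breaks[k + 1L]]
      reaches_end <- run[length(run)] == length(v)
      if (length(run) >= quiet_run || reaches_end) {
        t_end_quiet <- times[run[1L]]
        break
      }
    }
  }

  t_end <- min(t_end_entropy, t_end_quiet)
  if (!is.finite(t_end)) t_end <- times[length(times)]
  t_onset <- times[onset_idx]
  if (!(t_onset < t_zero && t_zero < t_end)) {
    abort("segmentation produced unordered time points.",
          class = "twitchtdi_segmentation_failure")
  }
  structure(list(t_onset = t_onset, t_zero = t_zero, t_end = t_end),
            class = "twitch_segmentation")
}

#' @export
print.twitch_segmentation <- function(x, ...) {
  cat(sprintf("<twitch_segmentation> onset %.4f s, zero %.4f s, end %.4f s\n",
              x$t_onset, x$t_zero, x$t_end))
  invisible(x)
}

# first element of `idx` starting a run of >= min_run consecutive indices
first_run_start <- function(idx, min_run) {
  if (!length(idx)) return(NA_integer_)
  if (min_run <= 1L) return(idx[1L])
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  for (k in seq_len(length(breaks) - 1L)) {
    len <- breaks[k + 1L] - breaks[k]
    if (len >= min_run) return(idx[breaks[k] + 1L])
  }
  NA_integer_
}

first_run_start_spaced <- first_run_start
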