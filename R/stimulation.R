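#' Electrical muscle stimulation train specification
#'
#' Describes the cyclic fatiguing EMS current pattern: each cycle ramps the
#' current from zero up to the working amplitude, holds it, ramps back down
#' and rests. During ramp and hold the stimulator delivers biphasic pulses at
#' `hold_frequency`; the working amplitude is the subject-specific current
#' producing 20% of maximum voluntary isometric torque (I20).
#'
#' Defaults reproduce the fatiguing protocol: 0.12 s ramp up, 0.5 s hold,
#' 0.12 s ramp down, 0.26 s rest (1 s cycle), 60 cycles (60 s train), 50 Hz
#' pulse trains (20 ms main pulse interval), 100 us pulse width per phase
#' with a 100 us interphase delay.
#'
#' @param ramp_up,hold,ramp_down,rest Phase durations of one cycle, s.
#' @param n_cycles Number of stimulation cycles in the train.
#' @param hold_frequency Pulse rate during the active part of a cycle, Hz.
#' @param phase_width Width of each phase of the biphasic pulse, s.
#' @param interphase_delay Delay between the two phases, s.
#' @param amplitude Working current amplitude (I20), mA.
#' @return An object of class `stimulation_train`.
#' @examples
#' st <- stimulation_train()
#' make_stimulation_train(st)$cycle_period
#' @export
stimulation_train <- function(ramp_up = 0.12, hold = 0.5, ramp_down = 0.12,
                              rest = 0.26, n_cycles = 60,
                              hold_frequency = 50, phase_width = 100e-6,
                              interphase_delay = 100e-6, amplitude = 30) {
  durs <- c(ramp_up = ramp_up, hold = hold, ramp_down = ramp_down, rest = rest,
            phase_width = phase_width, interphase_delay = interphase_delay)
  if (any(durs < 0)) {
    abort(sprintf("negative duration: %s",
                  paste(names(durs)[durs < 0], collapse = ", ")),
          class = "twitchtdi_invalid_argument")
  }
  stopifnot(n_cycles >= 1, hold_frequency > 0, amplitude >= 0)
  structure(
    list(ramp_up = ramp_up, hold = hold, ramp_down = ramp_down, rest = rest,
         n_cycles = as.integer(n_cycles), hold_frequency = hold_frequency,
         phase_width = phase_width, interphase_delay = interphase_delay,
         amplitude = amplitude),
    class = "stimulation_train"
  )
}

#' Sample a stimulation train's current envelope and pulse times
#'
#' Builds the piecewise-linear current envelope of the cyclic EMS train and
#' the biphasic pulse onset times within each cycle's active (ramp + hold +
#' ramp) window, at the train's `hold_frequency`.
#'
#' @param spec A [stimulation_train()] object.
#' @param rate Envelope sampling rate, Hz.
#' @return A list with `envelope` (tibble of `time_s`, `current_ma`),
#'   `pulse_times` (s), `cycle_period` (s) and `train_duration` (s).
#' @export
make_stimulation_train <- function(spec, rate = 1000) {
  stopifnot(inherits(spec, "stimulation_train"))
  cycle_period <- spec$ramp_up + spec$hold + spec$ramp_down + spec$rest
  train_duration <- spec$n_cycles * cycle_period
  times <- seq(0, train_duration, by = 1 / rate)
  phase <- times %% cycle_period
  # last sample belongs to the end of the final cycle, not the start of a new one
  phase[times == train_duration & train_duration > 0] <- cycle_period
  env <- numeric(length(times))
  up <- phase < spec$ramp_up
  env[up] <- spec$amplitude * phase[up] / spec$ramp_up
  hd <- phase >= spec$ramp_up & phase < spec$ramp_up + spec$hold
  env[hd] <- spec$amplitude
  dn <- phase >= spec$ramp_up + spec$hold &
    phase < spec$ramp_up + spec$hold + spec$ramp_down
  env[dn] <- spec$amplitude *
    (1 - (phase[dn] - spec$ramp_up - spec$hold) / spec$ramp_down)

  active <- spec$ramp_up + spec$hold + spec$ramp_down
  within_cycle <- seq(0, active, by = 1 / spec$hold_frequency)
  within_cycle <- within_cycle[within_cycle < active]
  pulse_times <- as.vector(outer(within_cycle,
                                 (seq_len(spec$n_cycles) - 1) * cycle_period,
                                 "+"))
  list(
    envelope = tibble(time_s = times, current_ma = env),
    pulse_times = sort(pulse_times),
    cycle_period = cycle_period,
    train_duration = train_duration
  )
}
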