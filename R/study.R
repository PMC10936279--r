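#' Fatigue and recovery model for synthetic studies
#'
#' Describes how twitch kinematics change with fatigue and recover with
#' rest, and how twitch torque relates to the waveform features:
#'
#' * During recovery, the amplitude deficit of post-fatigue twitch `k`
#'   follows the power law `min(1, recovery_b0 * k^recovery_b1)`, rescaled
#'   so that the first post-fatigue twitch is down by exactly
#'   `post_fatigue_drop`: the multiplier is
#'   `1 - post_fatigue_drop * (1 - min(1, b0 k^b1)) / (1 - b0)`. With the
#'   default `post_fatigue_drop = 1 - recovery_b0` the multiplier is the
#'   power law itself, `min(1, 0.614 k^0.236)`; `post_fatigue_drop = 0`
#'   gives the no-fatigue null.
#' * The time-to-zero (and total duration) of a fatigued twitch is inflated
#'   by `duration_inflation` scaled by the relative amplitude deficit (1 at
#'   the first post-fatigue twitch, declining as the muscle recovers).
#' * Twitch torque is a linear function of the five true waveform features
#'   (`torque_weights`, names matching the feature columns) plus Gaussian
#'   noise with SD `torque_noise_sd` (N m).
#'
#' @param baseline_amplitude Baseline gate-center peak velocity, m/s.
#' @param post_fatigue_drop Fractional amplitude drop at the first
#'   post-fatigue twitch, in [0, 1); 0 disables fatigue.
#' @param recovery_b0,recovery_b1 Power-law recovery coefficients.
#' @param duration_inflation Fractional time-to-zero increase at the full
#'   post-fatigue deficit.
#' @param torque_weights Named numeric vector of per-feature torque
#'   coefficients (N m per feature unit).
#' @param torque_noise_sd Torque noise SD, N m.
#' @param feature_jitter_cv Per-twitch multiplicative jitter (coefficient of
#'   variation) applied independently to amplitude, durations and gradient.
#' @return An object of class `fatigue_model`.
#' @export
fatigue_model <- function(baseline_amplitude = 0.02,
                          post_fatigue_drop = 1 - 0.614,
                          recovery_b0 = 0.614,
                          recovery_b1 = 0.236,
                          duration_inflation = 0.08,
                          torque_weights = c(peak_velocity_mps = 750,
                                             time_to_zero_s = 0,
                                             total_duration_s = 0,
                                             peak_vti_m = 4000,
                                             peak_strain_rate_per_s = 0),
                          torque_noise_sd = 0.5,
                          feature_jitter_cv = 0.05) {
  if (!(post_fatigue_drop >= 0 && post_fatigue_drop < 1)) {
    abort("`post_fatigue_drop` must lie in [0, 1).",
          class = "twitchtdi_invalid_argument")
  }
  stopifnot(baseline_amplitude > 0, recovery_b0 > 0,
            duration_inflation >= 0, torque_noise_sd >= 0,
            feature_jitter_cv >= 0)
  feature_names <- c("peak_velocity_mps", "time_to_zero_s",
                     "total_duration_s", "peak_vti_m",
                     "peak_strain_rate_per_s")
  w <- setNames(numeric(5), feature_names)
  w[names(torque_weights)] <- torque_weights
  structure(
    list(baseline_amplitude = baseline_amplitude,
         post_fatigue_drop = post_fatigue_drop,
         recovery_b0 = recovery_b0, recovery_b1 = recovery_b1,
         duration_inflation = duration_inflation,
         torque_weights = w, torque_noise_sd = torque_noise_sd,
         feature_jitter_cv = feature_jitter_cv),
    class = "fatigue_model"
  )
}

#' Amplitude multiplier of post-fatigue twitch k
#'
#' `min(1, recovery_b0 * k^recovery_b1)`; baseline twitches have
#' multiplier 1.
#'
#' @param fatigue A [fatigue_model()].
#' @param k Post-fatigue twitch index (1-based), vectorised.
#' @return Numeric multipliers in (0, 1].
#' @export
recovery_multiplier <- function(fatigue, k) {
  pmin(1, fatigue$recovery_b0 * k^fatigue$recovery_b1)
}

#' Synthetic study specification
#'
#' Layout of a synthetic fatigue-recovery study: per subject, a block of
#' baseline twitches (round 0) followed by `n_rounds` rounds of a fatiguing
#' stimulation train each followed by `n_recovery_twitches` recovery
#' twitches, mirroring the experimental schedule (5 baseline twitches; 1 or
#' 5 rounds; twitches every ~20 s over 2 min of rest).
#'
#' @param n_subjects Number of subjects.
#' @param n_baseline_twitches Baseline twitches per subject (default 5).
#' @param n_recovery_twitches Recovery twitches per round (default 5).
#' @param n_rounds Fatiguing rounds (1 or 5 in the protocol; any >= 1
#'   accepted).
#' @param seed Integer seed; identical seeds give identical studies.
#' @param subject_amplitude_cv Between-subject coefficient of variation of
#'   the baseline amplitude (lognormal).
#' @param velocity_noise_sd Additive white velocity noise on waveform-level
#'   records, m/s.
#' @param record_duration Length of each simulated record, s.
#' @param stim_time Stimulus time within each record, s.
#' @return An object of class `synthetic_study_spec`.
#' @export
synthetic_study <- function(n_subjects = 9,
                            n_baseline_twitches = 5,
                            n_recovery_twitches = 5,
                            n_rounds = 5,
                            seed = 1L,
                            subject_amplitude_cv = 0.15,
                            velocity_noise_sd = 5e-4,
                            record_duration = 1.2,
                            stim_time = 0.1) {
  stopifnot(n_subjects >= 1, n_baseline_twitches >= 1,
            n_recovery_twitches >= 1, n_rounds >= 1,
            velocity_noise_sd >= 0, record_duration > 0.5, stim_time > 0)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_baseline_twitches = as.integer(n_baseline_twitches),
         n_recovery_twitches = as.integer(n_recovery_twitches),
         n_rounds = as.integer(n_rounds),
         seed = as.integer(seed),
         subject_amplitude_cv = subject_amplitude_cv,
         velocity_noise_sd = velocity_noise_sd,
         record_duration = record_duration,
         stim_time = stim_time),
    class = "synthetic_study_spec"
  )
}

#' Generate a synthetic fatigue-recovery study with known ground truth
#'
#' Draws per-twitch kinematics from the fatigue model and study layout and
#' returns a study table with ground-truth features, torque, and (depending
#' on `level`) simulated signals:
#'
#' * `"features"` — ground-truth features only (fast; the per-twitch
#'   kinematic jitter is the only noise source).
#' * `"waveform"` — additionally a 1-kHz noisy gate-averaged velocity
#'   waveform per twitch (list-column `waveform`), emulating the output of
#'   the Doppler stage.
#' * `"rf"` — additionally a full RF scanline series per twitch
#'   (list-column `rf`), to be run through the Doppler stage.
#'
#' Torque is `sum(torque_weights * true features) + N(0, torque_noise_sd)`.
#' Identical `spec$seed` reproduces the study bit for bit.
#'
#' @param spec A [synthetic_study()] layout.
#' @param fatigue A [fatigue_model()].
#' @param kin Baseline [twitch_kinematics()] template (its
#'   `peak_velocity_amplitude` is replaced by the fatigue model's
#'   `baseline_amplitude`).
#' @param params An [acquisition_params()]; required for `level = "rf"`.
#' @param level Fidelity level: `"features"`, `"waveform"` or `"rf"`.
#' @return A tibble (the study table) with columns `subject`, `round`,
#'   `twitch_index`, `phase`, `multiplier`, `stim_time_s`, `torque_nm`, the
#'   five `true_*` feature columns, and signal list-columns per `level`.
#' @examples
#' st <- generate_study(synthetic_study(n_subjects = 2, n_rounds = 1, seed = 1),
#'                      fatigue_model(), level = "features")
#' dplyr::count(st, phase)
#' @export
generate_study <- function(spec, fatigue = fatigue_model(),
                           kin = twitch_kinematics(),
                           params = acquisition_params(),
                           level = c("features", "waveform", "rf")) {
  stopifnot(inherits(spec, "synthetic_study_spec"),
            inherits(fatigue, "fatigue_model"),
            inherits(kin, "twitch_kinematics"))
  level <- match.arg(level)

  withr_seed(spec$seed, {
    rows <- list()
    for (s in seq_len(spec$n_subjects)) {
      subj_amp <- fatigue$baseline_amplitude *
        exp(rnorm(1, 0, spec$subject_amplitude_cv) -
              spec$subject_amplitude_cv^2 / 2)
      sched <- rbind(
        data.frame(round = 0L, twitch_index = seq_len(spec$n_baseline_twitches),
                   phase = "baseline"),
        do.call(rbind, lapply(seq_len(spec$n_rounds), function(r) {
          data.frame(round = r, twitch_index = seq_len(spec$n_recovery_twitches),
                     phase = "recovery")
        }))
      )
      for (i in seq_len(nrow(sched))) {
        k <- sched$twitch_index[i]
        rel_deficit <- if (sched$phase[i] == "baseline" ||
                           fatigue$recovery_b0 >= 1) 0 else
          (1 - recovery_multiplier(fatigue, k)) / (1 - fatigue$recovery_b0)
        mult <- 1 - fatigue$post_fatigue_drop * rel_deficit
        infl <- 1 + fatigue$duration_inflation * rel_deficit
        cv <- fatigue$feature_jitter_cv
        jit <- exp(rnorm(4, 0, cv) - cv^2 / 2)
        te_i <- kin$expansion_duration * infl * jit[2]
        kin_i <- twitch_kinematics(
          onset_time = spec$stim_time + 0.05,
          expansion_duration = te_i,
          total_duration = max(kin$total_duration * infl * jit[4], 1.2 * te_i),
          peak_velocity_amplitude = subj_amp * mult * jit[1],
          depth_gradient = kin$depth_gradient * mult * jit[3]
        )
        truth <- true_twitch_features(kin_i)
        torque <- sum(fatigue$torque_weights * as.numeric(truth[1, ])) +
          rnorm(1, 0, fatigue$torque_noise_sd)
        row <- tibble(
          subject = s, round = sched$round[i], twitch_index = k,
          phase = sched$phase[i], multiplier = mult,
          stim_time_s = spec$stim_time, torque_nm = torque,
          true_peak_velocity_mps = truth$peak_velocity_mps,
          true_time_to_zero_s = truth$time_to_zero_s,
          true_total_duration_s = truth$total_duration_s,
          true_peak_vti_m = truth$peak_vti_m,
          true_peak_strain_rate_per_s = truth$peak_strain_rate_per_s
        )
        if (level == "waveform") {
          wf <- analytic_waveform(kin_i, spec$record_duration)
          if (spec$velocity_noise_sd > 0) {
            wf$values <- wf$values +
              rnorm(length(wf$values), 0, spec$velocity_noise_sd)
          }
          row$waveform <- list(wf)
        } else if (level == "rf") {
          p_i <- params
          p_i$n_pulses <- as.integer(ceiling(spec$record_duration * params$prf))
          ph <- build_phantom(p_i, density = 8,
                              seed = spec$seed * 1000L + s * 100L + i)
          row$rf <- list(simulate_rf_twitch(ph, kin_i, p_i, snr_db = 30))
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
    study <- dplyr::bind_rows(rows)
    attr(study, "spec") <- spec
    attr(study, "fatigue") <- fatigue
    attr(study, "kinematics") <- kin
    study
  })
}

#' Measure the waveform features of every twitch in a study table
#'
#' Applies the analysis chain appropriate to the study's fidelity level to
#' each twitch: [analyze_twitch()] for RF records, [analyze_waveform()] for
#' waveform records, or a pass-through of the ground-truth features for
#' feature-level studies. Twitches whose segmentation fails are dropped
#' with a warning.
#'
#' @param study A [generate_study()] table.
#' @param ... Passed to the per-twitch analyzers (segmentation thresholds).
#' @return The study table with measured feature columns
#'   (`peak_velocity_mps`, ..., `peak_strain_rate_per_s`) and segmentation
#'   times appended; signal list-columns are removed.
#' @export
measure_study_features <- function(study, ...) {
  stopifnot(is.data.frame(study))
  base_cols <- dplyr::select(study, -dplyr::any_of(c("rf", "waveform")))
  if ("rf" %in% names(study)) {
    feats <- purrr::imap(study$rf, function(rf, i) {
      tryCatch(analyze_twitch(rf, study$stim_time_s[i], ...),
               error = function(e) NULL)
    })
  } else if ("waveform" %in% names(study)) {
    feats <- purrr::imap(study$waveform, function(wf, i) {
      tryCatch(
        analyze_waveform(wf, study$stim_time_s[i],
                         strain_rate = study$true_peak_strain_rate_per_s[i],
                         ...),
        error = function(e) NULL)
    })
  } else {
    feats <- purrr::pmap(study, function(...) {
      r <- list(...)
      tibble(t_onset_s = NA_real_, t_zero_s = NA_real_, t_end_s = NA_real_,
             peak_velocity_mps = r$true_peak_velocity_mps,
             time_to_zero_s = r$true_time_to_zero_s,
             total_duration_s = r$true_total_duration_s,
             peak_vti_m = r$true_peak_vti_m,
             peak_strain_rate_per_s = r$true_peak_strain_rate_per_s)
    })
  }
  ok <- !purrr::map_lgl(feats, is.null)
  if (any(!ok)) {
    warn(sprintf("segmentation failed for %d of %d twitches; rows dropped.",
                 sum(!ok), length(ok)))
  }
  out <- dplyr::bind_cols(base_cols[ok, ], dplyr::bind_rows(feats[ok]))
  attr(out, "spec") <- attr(study, "spec")
  attr(out, "fatigue") <- attr(study, "fatigue")
  out
}
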