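# twitchtdi

Pulsed-wave **tissue Doppler imaging (TDI)** analysis of electrically
stimulated muscle twitches, for researchers studying EMS-induced muscle
fatigue. Electrical muscle stimulation corrupts surface EMG, the usual
fatigue monitor; ultrasound Doppler is electrically quiet. A single
scanline fired at kilohertz rate through the muscle belly yields tissue
velocities from pulse-to-pulse phase shifts, and the twitch velocity
waveform's features track fatigue, recovery and twitch torque.

The package implements the full measurement and analysis chain, with a
synthetic acquisition front end replacing the human experiment:

* **Simulation** — 1-D scatterer phantoms, Gaussian-pulse RF echo series
  under prescribed isometric twitch kinematics, EMS stimulation trains
  (1 s cycles: 0.12 / 0.5 / 0.12 / 0.26 s; 60 cycles; 50 Hz biphasic
  pulses), and complete multi-subject fatigue-recovery studies with known
  ground truth.
* **Velocity estimation** — analytic signal via FFT Hilbert transform and
  lag-one phase autocorrelation,

  $$ v(t,d) = \frac{c\,\Delta\phi(t,d)}{4\pi F_c T}, $$

  bounded by the Nyquist velocity $c\,\mathrm{PRF}/(4F_c)$, then 1 kHz
  block-average downsampling and unweighted averaging over the Doppler
  gate.
* **Twitch analysis** — automatic three-point segmentation (onset,
  velocity zero-crossing, end; spectral entropy with a 164-sample window
  and 0.7 cutoff guides the end point) and five waveform features: peak
  velocity, time-to-zero, total duration, peak velocity–time integral,
  and peak strain rate (1.925 mm axial smoothing, average spatial
  gradient over the gate).
* **Statistics** — per-subject baseline normalization, paired t-tests with
  Holm–Bonferroni correction, one-way repeated-measures ANOVA with
  partial η², power-law recovery trends $y = b_0 x^{b_1}$ fitted in
  log–log space, and per-subject stepwise regression of twitch torque on
  the features (p < .05 to enter, p > .10 to remove).

Functions are tibble-first and pipe-friendly; fitted objects have
`tidy()` / `glance()` methods and `autoplot()` / `plot_recovery()`
graphics.

## Worked example

Simulate one twitch acquisition and extract its features:

```r
library(twitchtdi)
library(dplyr)

params  <- acquisition_params()      # 6.66 MHz, 40 MHz fs, 10 kHz PRF, 15-35 mm gate
phantom <- build_phantom(params, density = 15, seed = 42)
kin     <- twitch_kinematics()       # 20 mm/s peak, 0.1 s time-to-zero
rf      <- simulate_rf_twitch(phantom, kin, params, snr_db = 30, noise_seed = 1)
analyze_twitch(rf, stim_time = 0.1)
#>   t_onset_s t_zero_s t_end_s peak_velocity_mps time_to_zero_s total_duration_s
#> 1    0.1505    0.251  0.4006             0.021         0.1004             0.25
#>   peak_vti_m peak_strain_rate_per_s
#> 1     0.0013                 1.6953
```

The segmentation lands on the prescribed onset (0.15 s) and zero-crossing
(0.25 s); the measured peak velocity (21 mm/s) sits slightly above the
20 mm/s material amplitude because the estimator measures at fixed depths
while faster tissue is advected through the gate — the closed-form
prediction of that effect is available as `expected_gate_waveform()`.

Generate a 9-subject, 5-round fatigue-recovery study and fit the torque
recovery trend:

```r
study <- generate_study(synthetic_study(n_subjects = 9, n_rounds = 5, seed = 1),
                        fatigue_model(), level = "waveform")
feats <- measure_study_features(study)
rec   <- normalize_to_baseline(feats) |> filter(phase == "recovery")
fit_power_trend(rec$twitch_index, rec$torque_nm)
#> <power_fit> y = 0.621 * x^0.2396  (R^2 = 0.810, F = 948.680, p = 2.732e-82, n = 225)
```

The fitted coefficients recover the generating recovery law
(b0 = 0.614, b1 = 0.236) from the noisy, segmented waveforms: normalized
torque drops ~38 % at the first post-fatigue twitch and climbs back as a
power law of twitch index. `run_pipeline(pipeline_config(), out_dir)`
executes the whole chain (simulate → features → statistics) and writes
`features.csv`, `report.json` and a run manifest.

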