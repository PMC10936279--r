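---
title: "Methods: tissue Doppler analysis of stimulated muscle twitches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue Doppler analysis of stimulated muscle twitches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twitchtdi)
```

## The problem

Electrical muscle stimulation (EMS) fatigues muscle rapidly, and surface
EMG — the usual tool for monitoring muscle state — is swamped by the
stimulation artifacts. Pulsed-wave tissue Doppler imaging (TDI) offers an
electrically quiet alternative: a single ultrasound scan line fired at
kilohertz rate through the muscle belly measures tissue velocity along the
beam from pulse-to-pulse phase shifts. During an electrically evoked
isometric twitch, the muscle cross-section expands and then passively
returns, producing a velocity waveform whose features (amplitude, timing,
strain rate) carry information about fatigue state and torque output.

`twitchtdi` implements that measurement chain end to end, with a synthetic
acquisition front end standing in for the human experiment: scatterer
phantoms and RF echo simulation, phase-autocorrelation velocity estimation,
twitch waveform segmentation and feature extraction, and the study-level
statistics (baseline normalization, paired tests with Holm–Bonferroni
correction, repeated-measures ANOVA, power-law recovery trends, per-subject
stepwise regression of torque on waveform features).

## Signal model and estimator

Each scanline is a sum over point scatterers of Gaussian-enveloped
sinusoids at the transducer center frequency $F_c$, delayed by the two-way
travel time $2d/c$. Echoes are converted to their analytic form by an FFT
Hilbert transform along fast time, and velocity follows from the phase of
the lag-one autocorrelation of the analytic signal,

$$ v(t, d) = \frac{c\,\Delta\phi(t, d)}{4\pi F_c T}, \qquad T = 1/\mathrm{PRF}, $$

with motion toward the transducer positive. Estimates are unambiguous up to
the Nyquist velocity $c\,\mathrm{PRF}/(4F_c)$ (0.58 m/s at the defaults);
faster motion wraps in sign, which the tests exercise deliberately.

Before the phase is taken, lag products are averaged over a 4-pulse sliding
ensemble and a 9-sample axial window (about one pulse length). This is the
usual variance-reduction practice: dark speckle pixels carry almost no
phase information of their own. The velocity field is then block-averaged
down to 1 kHz (a low-pass that emphasises the slow tissue velocities of
interest) and averaged without weighting across the Doppler gate to give
the 1-D twitch waveform.

### Accuracy limits of the estimator

Two properties of speckle physics matter for interpreting the tests:

* **Speckle gain noise.** For a single phantom realization, the compound
  echo's spectral centroid deviates from $F_c$, producing a multiplicative
  gain error on all velocities of roughly 1–2 % (SD) over a 20 mm gate.
  The estimator is unbiased over the speckle ensemble, so oracle tests
  that demand sub-percent accuracy average over small ensembles of
  independent phantoms (4–24 realizations); single-realization accuracy is
  separately bounded at the 2–5 % level.
* **Eulerian measurement.** The estimator reports velocity at fixed
  depths, while the kinematic model prescribes the motion of material
  points. With a depth gradient in peak velocity, faster tissue is
  advected through fixed pixels, raising the measured gate average by
  about 5 % at the defaults. This is physics, not error;
  `expected_gate_waveform()` and `expected_velocity_field()` evaluate the
  fixed-depth prediction in closed form (fixed-point inversion of the
  displacement map) and serve as the reference for all end-to-end
  recovery tests.

## The synthetic twitch and study

The paper-level protocol fixes the acquisition (6.66 MHz center frequency,
40 MHz sampling, PRF 10 or 12.5 kHz), the fatiguing train (1 s cycles:
0.12 s ramp up, 0.5 s hold, 0.12 s ramp down, 0.26 s rest; 60 cycles;
50 Hz pulses of 100 µs per phase with 100 µs interphase delay), the twitch
schedule (five baseline twitches, then five per recovery period, one or
five rounds), and the analysis constants (1 kHz analysis rate, 164-sample
spectral-entropy window with 0.7 cutoff, 1.925 mm / 100-sample strain-rate
smoothing). It does not state the twitch waveform shape or amplitude in
physical units, so those are package defaults, chosen once:

* gate-center peak velocity 20 mm/s, time-to-zero 0.1 s, total duration
  0.25 s — mm/s-scale velocities and a contraction time in the range of
  gastrocnemius twitches;
* a linear depth profile of peak velocity with gradient 1.5 s⁻¹, giving a
  known, constant ground-truth strain rate;
* Doppler gate 15–35 mm (a 20 mm span covering the muscle belly; wider
  gates also dilute Hilbert edge effects and speckle gain noise);
* additive white RF noise at 30 dB SNR; speed of sound 1540 m/s; Gaussian
  pulse with −6 dB fractional bandwidth 0.6.

The displacement bump is a Hann-squared profile with a piecewise-linear
time warp, i.e. two half-sine velocity lobes with the return amplitude set
by isometric closure (displacement returns exactly to zero; a single
velocity zero-crossing at onset + time-to-zero). All five features then
have closed forms, e.g. peak VTI $= 2 V_p T_e / \pi$.

Fatigue follows the printed recovery trend: the amplitude multiplier of
post-fatigue twitch $k$ is $\min(1,\, 0.614\,k^{0.236})$, i.e. an initial
drop of 38.6 % recovering as a power law, with time-to-zero inflated in
proportion to the remaining deficit (8 % at full deficit by default).
Twitch torque is a linear function of the true features plus Gaussian
noise; per-twitch kinematic jitter (5 % CV, independent for amplitude,
expansion time, total duration and gradient) and between-subject baseline
variation (15 % CV, lognormal) provide realistic dispersion.

`generate_study()` offers three fidelity levels. `"rf"` simulates full RF
per twitch and is used to validate the Doppler stage; `"waveform"`
synthesises the 1 kHz gate-averaged waveform with additive velocity noise
(0.5 mm/s) and runs segmentation and feature extraction — this is the level
used for study-scale statistics, because the Doppler stage's accuracy is
established separately and full RF at 450 twitches per study would dominate
runtime without adding information about the statistics under test;
`"features"` returns ground-truth features directly. At the waveform level
the strain-rate feature is carried through from the generator's kinematics
(with its own jitter), since it requires depth-resolved data.

## Automatic segmentation

The original analysis segmented waveforms manually with spectral entropy as
a guide; this package defines a fully automatic, reproducible rule with the
same three time points. Onset is the first sustained (≥ 5 ms) excursion of
$|v|$ above 3× the robust SD (MAD) of the pre-stimulus baseline; the
zero-crossing is the first sign change after the first peak of $|v|$,
located by linear interpolation; the end is the earlier of sustained
spectral entropy above 0.7 (Hann-tapered periodogram over positive
frequencies, window 164 samples, hop window/4, zero-variance windows
assigned entropy 0) or $|v|$ back at the onset threshold for ≥ 20 ms (a
sub-threshold run reaching the end of the record also counts, so records
that stop at the twitch end remain segmentable). All thresholds are
arguments. Segmentation is polarity-invariant — the velocity sign
convention depends on probe orientation — and time-shift equivariant, and
both properties are tested.

Peak VTI is taken as the absolute value of the running integral at the
zero-crossing so that either polarity yields a positive feature;
integration is trapezoidal on the 1 kHz grid without resampling.

## Statistics stage

All paper-level procedures are reproduced deterministically:

* normalization divides each measure by the subject's own baseline mean
  (guarded against zero baselines with an error naming subject and
  measure);
* paired t-tests use the Holm step-down adjustment (`p.adjust`), with the
  paired Cohen's d (mean difference / SD of differences; the variant is
  not stated in the source, so the simplest paired form is used);
* the one-way repeated-measures ANOVA is computed from the within-subject
  decomposition, $F = MS_{cond}/MS_{cond\times subj}$ and partial
  $\eta^2 = SS_{cond}/(SS_{cond}+SS_{err})$, without sphericity correction
  (none was reported); it is cross-checked against `aov` with an error
  stratum in the tests;
* the power recovery trend $y = b_0 x^{b_1}$ is fitted by OLS on
  $\log y \sim \log x$ — deterministic and consistent with reporting
  $R^2$, $F$ and $p$ as a regression — and is exactly scale-equivariant;
* stepwise regression starts from the constant model, enters the smallest
  partial-$F$ p-value below 0.05, removes any retained term above 0.10,
  breaks ties by lower p then column order, and skips rank-deficient
  candidates with a warning. Per the protocol it is run per subject on raw
  (unnormalized) features.

Two statistical facts discovered during validation are worth recording.
First, with five independent null candidates at `p_enter = .05`, a correct
forward entry admits at least one with probability $1 - 0.95^5 \approx
23\%$, so "empty model on null data" occurs in only ~77 % of simulations —
no correct implementation can exceed 90 %. Second, for half-sine twitches
peak VTI is an exact function of peak velocity and time-to-zero
($2 V_p T_e/\pi$), so torque support planted on those two features is not
identifiable against the VTI proxy; support-recovery simulations therefore
plant weights on peak velocity and peak strain rate, a pair with
independent variation.

## Problem sizes and numerical choices

Validation simulations use 20 mm gates at 10 kHz PRF with 0.6 s records
(6000 pulses, ~1000 depth samples), density 15 scatterers/mm, and phantom
ensembles of 3–24 realizations; study-level checks use 9 subjects × 5
rounds at the waveform level, with 10-seed medians for recovery-exponent
checks. Phantom margins default to 2 mm beyond the gate; scatterers driven
outside the margin are dropped with a warning. Downsampling bins are
guarded against floating-point boundary flips with a 1 ns epsilon; the
first velocity column is assigned at $T/2$ and final partial blocks are
dropped.

## Known limitations

The phantom is 1-D and single-scanline; no beamforming, no pennation-angle
geometry, no motor-unit electrophysiology, no potentiation dynamics. The
synthetic study's noise model (white RF noise, lognormal jitter) does not
reproduce physiological trial-to-trial structure, so passing tests
demonstrate correctness of the measurement and statistics chain, not
field performance on human data. The subject-level percentages and $R^2$
ranges of the original experiment derive from undeposited human data and
are not reproduction targets.
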