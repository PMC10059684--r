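---
title: "Quantifying directional EEG traveling waves: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying directional EEG traveling waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

An oscillation whose phase advances systematically along a spatial array of
sensors is a traveling wave. On a line of 7 electrodes running from occipital
to frontal sites, a wave appears as an oblique stripe in the electrode x time
map; its 2D discrete Fourier transform concentrates energy in the quadrant
whose spatial- and temporal-frequency signs match the propagation direction.
`twaves` quantifies this as follows, per 500-ms window (250-ms overlap)
sliding over each trial:

1. 2D-DFT of the 7 x 128 space-time map; for each temporal frequency between
   2 and 45 Hz (2-Hz grid at 256 Hz), take the maximum **power** over spatial
   frequencies in the forward quadrant (`FW`) and in the conjugate quadrant
   (`BW`). The spatial-DC line is excluded: a spatially uniform oscillation
   carries no direction. With rows ordered occipital to frontal and the usual
   DFT sign convention, "forward" is the quadrant where the spatial and
   temporal indices have opposite signs; the convention is locked by a test
   against the generator's definition of a forward wave (positive phase step
   toward frontal electrodes).
2. Repeat after randomly permuting the electrode rows (default 100 shuffles;
   all 5040 permutations available). Shuffling preserves every channel's
   spectrum - the surrogate keeps the 1/f trend and any alpha peak - but
   destroys spatial order, so it is a direction-free null with matched power.
3. Express the wave amount as `10*log10(FW / FW_ss)` decibels, where `FW_ss`
   is the surrogate aggregate; 0 dB means indistinguishable from the null.
   dB is computed per window, then averaged across windows and trials.

Two numerical choices deserve emphasis:

* **Geometric surrogate mean.** Under the null the raw maximum is
  exchangeable with every shuffle maximum, so averaging surrogate *logs*
  makes E[dB] exactly zero; averaging raw maxima first would leave a
  Jensen-type bias of about -0.5 dB on every null cell. We therefore
  aggregate shuffles by their geometric mean.
* **Power, not amplitude, maxima.** The quadrant statistic is the squared
  magnitude. On the amplitude scale the surrogate ratio for a clean plane
  wave saturates near +2 dB (a shuffled coherent wave still projects ~60-70%
  on its best spatial frequency), which compresses the dynamic range of the
  measure.

A consequence worth knowing when interpreting output: a strong wave in one
direction *suppresses* the opposite-direction dB below zero, because the
shuffles redistribute its energy into both quadrants and inflate the
opposite surrogate. Relatedly, forward dB can correlate *negatively* with
anything that scales backward-wave amplitude, since both directions share
the same surrogate denominator. The resting-state correlation grid of the
human data shows exactly this sign pattern (positive backward, weakly
negative forward correlations with alpha power), and the simulation
reproduces it without any forward-specific coupling.

The exhaustive surrogate satisfies `FW_ss == BW_ss` bit-for-bit: the spatial
DFT table is built conjugate-symmetric by construction, making the backward
value of a permutation bit-identical to the forward value of the reversed
permutation, and exhaustive averages are computed by sorted summation. For
the same reason, reversing the electrode order of any map swaps the forward
and backward spectra exactly; time reversal swaps them up to FFT rounding
(~1e-15 relative).

## Statistics

The analysis unit is the band-averaged dB value per subject, homologous line
pair, laterality and direction (bands: theta 4-7, alpha 8-12, low beta
13-24, high beta/gamma 25-45 Hz, averaging the DFT bins whose centers fall
in the band). Lateral pairs are normalized by subtracting the mean of their
contralateral and ipsilateral values, removing per-line power offsets; the
midline is reported unnormalized and excluded from laterality contrasts.

* **Block analysis** (event-free trials): repeated-measures ANOVA with
  DIRECTION, LINE (distance from the midline) and LATERALITY as within
  factors and subjects random, via `aov` error strata. We report classical
  F, p and partial eta-squared plus an *approximate* `BF10` from BIC
  differences of maximum-likelihood random-intercept models with and without
  the term (terms containing it removed alongside, respecting marginality).
  This is not a model-averaged Bayesian ANOVA; it preserves effect ordering
  in calibration tests and is labeled approximate everywhere. Random slopes
  are deliberately not modeled (the human-data analyses note classical,
  intercept-only results alongside their Bayesian models).
* **Wave-power correlation**: Morlet-wavelet power (30 log-spaced
  frequencies over 1-45 Hz; cycles interpolated linearly in log-frequency
  from 1 to 20; edge samples within half a wavelet support excluded;
  wavelets amplitude-normalized so a sinusoid of amplitude A yields power
  A^2), averaged over the alpha grid frequencies and over the occipital /
  frontal region electrodes of each hemisphere - the same electrodes the
  line analysis uses (the 2 most occipital and 2 most frontal positions of
  each lateral line). Between subjects: Pearson r with the JZS default-prior
  correlation Bayes factor by adaptive quadrature (checked against a
  Riemann-sum oracle to 1%). Within subjects: trial-by-trial r per condition,
  Fisher-combined p (`T = -2*sum(ln p)` against chi-square with 2N df,
  p floored at 1e-300 before the log), and a default-prior Bayes-factor
  t test of the Fisher-z-transformed r values against zero.
* **Event analysis**: waves in the 500 ms before and after target/distractor
  onset, laterality relative to the *stimulus* side (targets appear on the
  attended side, distractors opposite), pair-normalized, with DIRECTION x
  EVENT and DIRECTION x OUTCOME ANOVAs and line x time dB maps around onset.
  Trials with onsets closer than one window to an epoch edge are skipped and
  counted.

## The synthetic world

The generator (`sim_config()` / `simulate_experiment()`) states the emulated
experiment; its defaults are the stated conditions, not tuning knobs:

* 5-s trials, 256 Hz, 64-channel BioSemi-style montage plus 3 EOG channels;
  600 trials per subject (300 per attended side) at full scale; 1/f
  background (exponent 1) of unit standard deviation per channel; events in
  half the trials, 100 ms long, onset uniform in [0.5 s, 4.4 s]; hit rate
  0.8 (the staircase that held human accuracy near 80% is replaced by this
  direct parameter).
* **One traveling wave per hemisphere, direction and band**, with each
  electrode's phase set by its occipito-frontal position (the line set
  places shared electrodes at consistent positions). Overlapping lines thus
  see one coherent wave rather than interfering per-line copies - the
  physically sensible reading, and necessary for occipital electrodes shared
  by all five lines of a hemisphere. Amplitudes: alpha 0.5 per direction
  (10 Hz, phase step pi/4 per electrode), theta-forward 0.3 (6 Hz),
  low-beta-backward 0.25 (18 Hz), gamma-forward 0.15 (32 Hz) - chosen once
  to put the midline profile in the same +-1-3 dB range as resting human
  data, with signal-to-noise that makes a 16-subject experiment decisively
  informative.
* **Attention**: gains of 1.5 multiply contralateral-forward and
  ipsilateral-backward alpha amplitude (1 = null world). A standing
  (spatially uniform per hemisphere, hence direction-invisible) alpha
  oscillation of amplitude 1 carries the classical power lateralization
  (ipsilateral gain 1.2).
* **Wave-power coupling**: the trial log-amplitudes of the coupled wave
  component (backward-contralateral by default) and of the standing alpha
  share a Gaussian latent factor with correlation exactly `rho`
  (`wave_power_coupling`, default 0.3); the wave-side loading scales with
  sqrt(rho) so that at rho = 0 the wave amplitude is constant across trials.
  This keeps the null exactly clean: the wave itself carries alpha power, so
  any residual wave-amplitude variability at rho = 0 would induce a *true*
  correlation between wave dB and measured power.
* **Hits and misses**: Bernoulli(0.8) by default. With `hit_slope > 0`,
  event trials draw a lognormal attention factor that multiplies
  contralateral-forward (and divides ipsilateral-backward) alpha amplitude
  for the whole trial, and the hit probability follows a logistic link on
  its log - so misses co-occur with reduced contralateral forward waves,
  visible both before and after onset, as in the human line x time maps.
* **Events** add a 100-ms broadband burst under a 10-ms-sd Gaussian envelope
  on the occipital electrodes contralateral to the stimulus (the human data
  give no model of the evoked response; this is our choice). EOG channels
  carry measurement noise and, in a configurable fraction of trials,
  150-unit saccade-like ramps to exercise rejection.

What a green test does *not* establish: the generator has no volume
conduction or source geometry (channels outside the lines receive background
only), no flicker-locked activity (the 160-Hz flicker of the original
stimulus is above the analysis Nyquist and never analyzed), phase-coherent
waves spanning a whole hemisphere (real waves are patchier), and trial
variability only where stated. Detection rates measured here are about the
pipeline's correctness, not about human effect sizes.

## Preprocessing

The chain mirrors standard practice for such recordings: integer-factor
decimation with an anti-alias FIR, zero-phase windowed-sinc FIR high-pass
(>1 Hz) and band-stop (47-53 Hz), sample-wise average reference over EEG
channels (EOG excluded), epoching from -500 ms to trial end, and rejection
of trials whose EOG exceeds 100 uV peak-to-peak or a 50 uV step between
adjacent 100-ms means (thresholds are conventional and exposed; the source
pipeline states none). All filters are symmetric FIR kernels applied with
delay compensation: the spatial phase gradient *is* the measurement, so no
filter may introduce direction-dependent group delay. No DSP package is
available in the target environment, so the windowed-sinc designs are
written out in `R/preprocessing.R` and verified by their measured frequency
response in the tests (>=20 dB at 50 Hz; passband flat to 0.5 dB).

## Degenerate inputs and edge rules

Aliased phase steps (|step| >= pi) and temporal frequencies at or above
Nyquist are rejected at construction. Maps with NAs are refused. Bands that
cover no DFT bin, regions with no channels, missing electrode labels and
incomplete line pairs raise configuration errors naming the offender.
Epoch windows outside the recording name the offending trial. Surrogate
shuffling permits the identity permutation (probability 1/5040), preserving
exchangeability. Trials shorter than one analysis window are refused.

## Known limitations

Sensor-level only - no source modeling, and the measure cannot distinguish a
cortically traveling wave from moving dipole projections. Lines only - no
full-scalp 2D wave fitting. The exact electrode composition of the 10
lateral lines in the human studies is not published; the default set is a
faithful but unverifiable reconstruction on a BioSemi-64 montage, shipped as
an editable CSV. Bayes factors for ANOVA terms are BIC approximations, not
the model-averaged values a JASP analysis would produce; the correlation and
t-test Bayes factors use conventional default priors whose scale the human
analyses do not state, so numeric equality with published BF values is not
asserted anywhere.
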