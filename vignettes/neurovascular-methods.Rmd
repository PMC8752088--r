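---
title: "Methods: spectroscopic inversion, haemodynamic metrics and the synthetic forward model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectroscopic inversion, haemodynamic metrics and the synthetic forward model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurovasc)
```

## The spectroscopic model

2D-OIS infers haemoglobin concentration changes from how strongly cortical
tissue absorbs light at a few visible wavelengths. The package works in
natural-log optical density throughout: attenuation is
`ΔA = −ln(I / I_baseline)` per pixel, wavelength and frame, with the baseline
the per-pixel mean over a user-chosen window (default: the 4 s preceding the
first stimulus onset). The inversion assumes the modified Beer–Lambert law

`ΔA(λ) = L(λ, S) [ε_HbO(λ) Δc_HbO + ε_HbR(λ) Δc_HbR]`

and solves it per sample by ordinary least squares over the recorded
wavelengths (at least two with linearly independent extinction rows; the
default instrument set is 494, 560, 575, 595 nm, and a design condition
number above 1e8 is rejected with a diagnostic). No non-negativity
constraint is imposed on the concentration changes: evoked washout makes
ΔHbR genuinely negative. `ΔHbT = ΔHbO + ΔHbR` holds identically because HbT
is computed as the sum. Fractional outputs divide each component by its own
assumed baseline (`HbO0 = S0·c0`, `HbR0 = (1−S0)·c0`, defaults
`c0 = 100 µM`, `S0 = 0.70`); fractional changes are insensitive to the
assumed `c0`, which cancels in the ratio when the underlying signal is
itself a fractional modulation.

### Optical constants

`inst/extdata/extinction.tsv` ships oxy/deoxy molar extinction spectra at
1 nm from 450–650 nm, already converted to natural-log base. The file is a
documented synthetic reconstruction: a spline through ~20 anchor wavelengths
of the standard published in-vitro tetramer compilations, accurate to about
10% and preserving the diagnostic features (Q-band peaks at 542/577 nm, the
560 nm dip, the 555 nm HbR maximum, isosbestic points near 500/548/569/586
nm, HbR dominance in the red). For self-consistent simulation and recovery —
the mode in which this package is validated — only internal consistency
matters; for absolute quantification of real recordings a measured table can
be supplied via `read_spectra()`.

Pathlengths use a two-parameter diffusion approximation,
`L(λ, S) = 1 / (2 √(µa (µa + µs')))` with `µa = c0 [S ε_HbO + (1−S) ε_HbR]`
and `µs'(λ) = a (λ/560)^(−b)` (defaults `a = 17 cm⁻¹`, `b = 1.2`,
brain-like). This yields ~300 µm of path at 560 nm rising toward the red,
the behaviour Monte-Carlo tissue models produce, without shipping or
requiring such a simulation. The table is computed in code on a saturation
grid (0.05–1.00 in 0.01 steps) and is overridable from TSV; wavelength
look-ups require exact matches (no silent interpolation across the
wavelength grid), saturation look-ups interpolate linearly and clamp at the
grid edges.

### Path-length scaling

When saturation departs from `S0` (most dramatically during spreading
depression), pathlengths looked up at `S0` are wrong. `plsa_refine()`
iterates: invert with pathlengths at the current per-sample saturation
estimate, update `S = HbO/(HbO + HbR)` from the recovered absolute
concentrations, look up again. Iteration stops when the maximum absolute
change in fractional HbT drops below `tol = 1e-4` or after `max_iter = 20`
passes; non-convergence returns the last iterate flagged, and saturation
estimates outside [0.05, 0.99] are clamped and counted. Two genuinely open
design points, decided here: saturation is updated *per pixel and time
sample* (not as a single global estimate), and the scheme is an
iterate-until-stable refinement rather than a joint fit — with a
saturation-flat table it reduces exactly to the single-pass inversion,
and `tol = Inf` returns the first iterate.

## Haemodynamic metrics

*Activation maps* subtract the baseline-window mean from the
stimulus-window mean of fractional HbT per pixel;
`trial_activation_map()` averages one map per trial across a session, which
is what makes thresholding reliable at realistic single-trial noise. The
*automated ROI* keeps pixels above the map's spatial mean + 1.5 spatial SD —
the SD is deliberately the spatial SD of the map itself, making the rule
invariant to positive rescaling — then keeps the largest 8-connected
component so each session yields one region. User-drawn masks bypass this
entirely.

*Evoked metrics* re-baseline each trial epoch to its own pre-window mean,
average point-wise, and report: peak (maximum deviation for HbT/HbO; for
HbR the signed extremum of largest magnitude, so a triphasic trace reports
whichever phase dominates), time to peak, rise time defined as the
10%→90% span of the peak deviation (interpolated between samples;
configurable fractions, since "rise time" has no universal definition), and
trapezoid AUC over onset → onset + stimulus + 10 s. A flat trace reports
peak 0 with absent times. The HbR shape classifier calls a trace triphasic
when a positive deflection precedes the negative washout, both exceeding
2 SD of the pre-onset trace and sustained for ≥3 consecutive samples — the
run-length requirement keeps isolated noise excursions from counting as
deflections, holding the false-positive rate on pure-noise traces below 5%.

*CSD metrics*: onset is the first post-insertion time with fractional HbT
below 0.95 sustained ≥2 s; the event reports the dip minimum, the rebound
maximum between dip and late window, the mean over a late reporting window
(default 625–1250 s after insertion, truncated and flagged when the
recording is shorter), and time to sustained recovery, defined as entering
1.0 ± 0.02 and staying for 60 s — a computable criterion standing in for
qualitative "recovered to baseline" language. Wavefront arrival per pixel is
the first crossing of half that pixel's own dip amplitude (robust to
amplitude variation across the field); speed is the inverse slope of
arrival time on distance from the origin with the regression R² as fit
quality. Fields whose fitted slope is non-positive or whose implied
traversal is under one frame period are flagged non-propagating rather than
assigned a meaningless speed; fewer than 10 arrivals yields an absent speed.

*MUA*: traces are high-passed at 500 Hz with a 4th-order zero-phase
Butterworth (the filter family/order is unstated in common protocol
descriptions; zero-phase avoids latency shifts), thresholded per channel at
the baseline mean + 1.5 baseline SD of the filtered trace, and events
counted per 100 ms bin as *upward threshold crossings* — one spike counts
once regardless of its width; the supra-threshold-samples alternative and a
rectified (both-sides) variant are available as options. Fractional MUA
divides each channel's bin counts by its mean baseline bin count.
Per-channel thresholds are used (pooling across channels is the other
reading of the rule; per-channel is robust to impedance differences).

*Coupling*: per trial, the peak fractional MUA (channel-averaged, stimulus
window) is paired with the peak fractional HbT (stimulus + post window),
and the relation fitted by OLS of y on x with R² the squared Pearson
correlation — matching the printed line-equation convention of coupling
scatter plots, rather than orthogonal regression. Stimulus-duration
clusters are pooled by default; per-cluster fits are a filter away.

## The synthetic forward model

The simulator exists so each stage above can be validated by parameter
recovery. It emulates: evoked fractional HbT as a gamma-variate kernel
convolved with the stimulus boxcar, renormalised in time and amplitude so
the configured `time_to_peak` and `peak_fraction` are exact, plus a delayed
sharper gamma undershoot that resolves within a trial; HbO carrying 1.25×
the HbT change so HbR shows washout, with an optional early HbR bump
(compensated in HbO) for the triphasic mode; CSD as a radially symmetric
travelling profile — Gaussian constriction dip, Gaussian rebound, logistic
onset of a prolonged undershoot decaying exponentially to baseline — delayed
by distance/speed per pixel; reflectance rendered through the same
Beer–Lambert forward model with optionally saturation-dependent true
pathlengths and multiplicative Gaussian noise (shot-noise-like, default 1%);
and extracellular voltage as unit-SD Gaussian noise plus Poisson-timed
stereotyped biphasic spikes (Gaussian-derivative pulses, zero-mean and
band-limited to the spiking band) whose rate multiplies by `evoked_gain`
during stimulus windows. Every generator is a pure function of its
configuration and seed; identical inputs are bit-identical.

What it deliberately does not emulate: vascular anatomy (the real CSD wave
is vessel-structured; the metrics under test are insensitive to the
symmetry), heartbeat/respiration artefacts and 1/f drift, anaesthesia-state
fluctuations, electrode drift and stimulus artefacts, and biophysical CSD
mechanisms (ion dynamics, neural silencing). Passing recovery tests
therefore demonstrates correctness of the analysis chain under its own
model assumptions, not robustness to every artefact of in-vivo data.

### The MUA counting regime

A point worth making explicit: with Gaussian background noise, upward
crossings of a threshold only ~1.5–2.5 noise SDs up occur hundreds of times
per second (Rice's formula), which would swamp any spike-rate signal. The
1.5 SD rule measures *rate* only because the SD in it is the SD of the
*spiking trace*, which baseline spiking inflates well beyond the noise
floor. The simulator defaults (10 events/s/channel baseline, spike peaks
50× noise SD, 1.2 ms width) place the threshold ~5 noise SDs above the
noise floor and safely below both lobes of the filtered spike, so counts
are spike-driven (a constant two crossings per spike) and fractional MUA
tracks the underlying rate gain. At materially lower SNR the same rule
degenerates into counting filtered noise — a property of the counting rule,
not of this implementation.

## Numerical choices and test problem sizes

Defaults in brief: natural-log OD; baseline 100 µM at 70% saturation;
baseline window 4 s pre-stimulus; ROI `k_sd = 1.5`; PLSA `tol = 1e-4`,
`max_iter = 20`, saturation clamp [0.05, 0.99]; MUA 500 Hz/4th-order
zero-phase, 100 ms bins, `k = 1.5`, upward crossings; CSD dip threshold
0.05 sustained 2 s, recovery band ±0.02 for 60 s, late window 625–1250 s;
evoked rise fractions 10–90%, AUC post-window 10 s; simulation grid
64×64 px at 50 µm pitch, 5 Hz imaging, 25 kHz ephys, 1% reflectance noise.

The validation suite scales problem sizes to desk scale while keeping the
generators' statistical parameters at their defaults: spectral round trips
run on the full 64×64 grid; ROI recovery uses 16×16-pixel sessions with 8
trials per seed across 20 seeds; evoked recovery uses 30-trial ROI-level
series with measurement noise of 0.002 fractional units (the ROI-mean noise
the full imaging chain delivers at 1% reflectance noise over ~300 pixels);
CSD speed recovery uses 24×24 grids at 2 Hz; MUA recovery uses 8 channels
at 10 kHz over 50 trials; coupling coverage uses 200 simulated tables of 60
trials. The end-to-end demo configuration (`demo_config()`) completes in
well under a minute on one CPU.

## Known limitations

Two chromophores only (no cytochrome oxidase or scattering-change term);
the diffusion pathlength model is a smooth stand-in for tissue-specific
Monte-Carlo tables; the extinction table is a documented reconstruction, so
absolute micromolar outputs from real data should not be quoted against it;
group-level inference (ANOVAs, post-hoc comparisons) is out of scope — the
exported tables are designed to feed standard statistical tooling; and the
CSD detector assumes a single episode per recording.
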