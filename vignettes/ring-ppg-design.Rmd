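---
title: "Designing rotation-robust ring PPG layouts: models and methods"
author: "ringppg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing rotation-robust ring PPG layouts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringppg)
```

## The problem

A smart ring measures photoplethysmography (PPG) by shining an LED into the
finger and detecting back-scattered light at a photodiode (PD) on the same
circumference. Unlike a wrist strap, a ring rotates freely during wear, so
the LED-PD pair samples ever-changing tissue paths. The design question this
package addresses is: *which angular separation between LED and PD keeps the
signal informative under arbitrary rotation?*

The working assumption, supported by the capillary-origin view of the PPG
signal, is that signal quality tracks the fraction of *detected* light that
traversed the capillary-rich microcirculation layer. A layout is scored by
simulating photon transport for every (LED position, PD position) pair on an
angular grid, and aggregating the microcirculation traversal fraction over
all ring positions that share the same LED-PD angle — because rotation maps
a fixed layout onto exactly those positions.

## The finger model

The default model is a cylinder of 19.2 mm total diameter: a 0.6 mm
epidermis (annulus 9.0–9.6 mm), a 1 mm dermis (8.0–9.0 mm) and a 16 mm
diameter microcirculation region, containing four blood vessels of 1.2 mm
diameter and a central bone. Capillaries are treated as uniformly
distributed within the dermis and microcirculation layers, so those layers
carry blended tissue/blood optical properties rather than resolved
capillaries.

Two choices are deliberately explicit because anatomy references do not pin
them down:

* **Vessel and bone placement.** Digital arteries run along the sides of
  the finger; the default places two volar arteries at ±30° from the volar
  midline and two dorsal veins at ±30° from the dorsal midline, centered at
  6.5 mm radius, with a 3 mm radius central bone. All positions and radii
  are overridable through a JSON config (`read_finger_config()`).
* **Three dimensions.** The simulation domain is a 3-D cylinder of 20 mm
  axial length with absorbing end caps, although the design question is
  cross-sectional. Two-dimensional transport distorts path-length
  statistics, so the third dimension is kept; the default axial length is
  long enough that end-cap losses are a small perturbation for ring-scale
  source-detector separations.

**Optical properties.** The packaged coefficient table
(`default_optics_table()`) carries absorption, scattering, anisotropy and
refractive index per region at 550, 628 and 940 nm. These are *literature
defaults* assembled from standard skin-optics compendium values, flagged as
such in the object, and user-replaceable. Quantitative reproduction of any
particular published traversal table depends on that study's coefficient
set; rankings and symmetry properties are the transferable results. All
interior indices default to 1.40 (index-matched interior), so Fresnel
physics acts only at the skin–air boundary; the kernel itself handles
arbitrary per-region index mismatches.

## The transport kernel

`run_simulation()` runs a weighted (implicit-capture) Monte Carlo:
exponential free paths at the local attenuation coefficient,
Henyey–Greenstein scattering (the de facto tissue phase function; the
anisotropy parameter g is the mean scattering cosine), per-interaction
weight deposition `mu_a/mu_t`, and Russian roulette below a weight of 1e-4
with survival probability 0.1. Geometry stepping is exact: the distance to
every cylindrical surface and end cap is solved in closed form per step, so
no voxelization error enters. Boundaries with mismatched refractive indices
reflect or refract photons by the unpolarized Fresnel equations, with total
internal reflection beyond the critical angle.

Detection is geometric: a photon that exits the outer boundary within the
PD patch (default 10° of arc by 2 mm axial, flush on the epidermis, any
exit angle) contributes its weight to the detected tally. A photon is
counted as having traversed a region if any transport sub-step lay inside
it; the headline `micro_fraction` is the detected-weight-weighted share
(a photon-count ratio is available via `count_ratio = TRUE`; the two agree
in expectation but not per run).

Numerical choices worth knowing:

* **Exact per-run weight balance.** Roulette survival boosts are debited
  from the absorbed tally, so launched = absorbed + escaped + detected holds
  to floating-point rounding on every run, not just in expectation. The
  absorbed tally remains an unbiased estimator.
* **Reproducibility.** Each photon draws from its own counter-derived
  substream (splitmix64-seeded xoshiro256**), so results are bit-identical
  for a fixed seed independent of execution order. Sweeps derive one seed
  per cell (`base_seed * 1000 + cell_index`) and are restartable.
* **Step cap.** Photons exceeding 1e5 steps are tallied as absorbed and
  counted; in default runs this count is zero.
* **NaN is an answer.** Layouts where no photon reaches the PD report
  `micro_fraction = NaN` rather than erroring; angle aggregation averages
  over the non-NaN ring positions and is NaN only when all positions are.

The desk-scale default is 1e5 photons per cell (seconds per cell on one core);
production-scale photon counts (5e7) are a config option, not the default,
and change only the standard errors, not the estimators.

## Layout sweep and ranking

`sweep_layouts()` fills the (LED angle × PD angle) grid — 12 × 12 cells at
the 30° manufacturing resolution, 144 placements — and
`aggregate_by_angle()` pools cells by LED-PD angle Δ = (PD − LED) mod 360,
reporting the mean and standard deviation of the traversal fraction over
the ring positions sharing Δ. `rank_angles()` orders angles by mean
fraction, breaking ties toward lower dispersion (rotation robustness) and
then smaller angle. A left-right symmetric model must produce
mean(Δ) ≈ mean(360° − Δ); this mirror symmetry is asserted in the tests
within Monte Carlo error, and is visible in the packaged reference table
(e.g. 0.878 vs 0.876 at 60°/300° for green light).

The packaged reference table (`reference_angle_table()`) reports published
per-angle traversal means for the three wavelengths from a 5e7-photon
simulation on an anatomical model; it ranks 60° first at all three
wavelengths and is used as a fixture for the ranking machinery, not as
something the desk-scale runs are expected to reproduce numerically.

## Signal-quality indices and the figure of merit

Records are split into non-overlapping 6-second segments (at the device's
100 Hz sampling rate, 600 samples) and band-pass filtered 0.5–5 Hz with a
4th-order Butterworth applied forward-backward (zero phase, so pulse
morphology is not skewed). Per segment the package computes:

* **AC** — mean over the six 1-s windows of the filtered max−min excursion;
* **DC** — mean of the *raw* segment (the static level, in ADC units);
* **PI** — AC/DC, the perfusion index (undefined when DC = 0);
* **SNR** — the literal in-band/residual power ratio in dB, using the raw
  segment high-passed at 0.5 Hz and low-passed at 5 Hz;
* **SPSD, KPSD** — skewness- and kurtosis-type sums of the standardized
  one-sided FFT power values (no 1/NF factor; the session normalization
  absorbs scale);
* **STDperiods, STDpeaks** — standard deviations of the autocorrelation
  peak-to-peak intervals and peak heights.

The figure of merit for a segment is

$$\mathrm{FoM} = \frac{PI \times AC \times S_{PSD} \times K_{PSD}}
{STD_{periods} \times STD_{peaks}}$$

computed after min–max normalizing each index to [1e-6, 1] across the
session's unflagged segments (an index constant across the session
normalizes to 1). The session summary is the mean ± SD over segments. SNR
is reported alongside but does not enter the FoM.

Decisions embedded there, made where the procedure is underdetermined:

* **Normalization scope.** Min–max per index across the session's
  segments, floored at 1e-6 to keep products positive and the denominator
  finite. Consequence: FoM magnitudes are session-relative and absolute
  values are not comparable across studies — only orderings are used.
* **Autocorrelation estimator.** One-sided, *unbiased* (each lag divided
  by its overlap length) and normalized by lag zero, with lags capped at
  half the segment. The unbiased form is what makes the exactly-periodic
  case clean: equal peak heights of exactly 1 and equal spacings, hence
  both periodicity SDs exactly zero. Peaks are integer-lag local maxima
  with topographic prominence ≥ 0.1 and ≥ 0.25 s spacing (both exposed as
  arguments).
* **Degenerate segments are flagged, not fudged.** DC = 0, a flat
  spectrum, fewer than the required autocorrelation peaks, or an exactly
  zero periodicity SD (a strictly periodic segment makes the denominator
  degenerate) exclude a segment from the FoM; an all-flagged session is an
  error.
* **The SNR formula is kept literal.** Its denominator subtracts two
  residual powers and is dominated by −DC² whenever the raw segment has an
  appreciable mean, in which case the SNR is NaN by construction. This is
  reported as the defined degenerate outcome rather than silently
  redefined; on zero-mean in-band test signals the formula behaves and is
  monotone in true noise level.
* **Edge transients are intrinsic.** A 0.5 Hz corner on a 6-s segment
  implies an impulse response that is long relative to the segment; no
  padding scheme removes in-band edge error entirely. The filters demean,
  odd-reflection pad by half a segment, and run forward-backward; mid-band
  tones pass within ~1 % mid-segment, and indices that average across the
  segment (AC, PI) absorb the residual edge effect to within a few
  percent.

## Heart rate

The HR path band-passes 0.5–8 Hz (zero phase, 4th-order design), detects
systolic peaks with an adaptive threshold — 0.5 × a rolling 3-s
90th-percentile amplitude envelope, 0.25 s refractory period, taller peak
winning ties — and reports HR = 60 / mean inter-beat interval. The
envelope-tracking threshold is what makes detection robust to
beat-to-beat amplitude alternation and slow perfusion drift; all its
constants are exposed as arguments. `hr_series()` produces a windowed HR
time series (10 s windows, 5 s hop by default) and
`score_against_reference()` computes the mean absolute error in bpm and
the percentage of windows within 3 bpm against a reference series.

## The synthetic generator

`synth_ppg()` provides the ground-truthed test substrate: beats are a
systolic Gaussian plus a delayed dicrotic Gaussian (relative amplitude
0.35, delay 0.35 and widths 0.09/0.12 of the beat interval — fixed,
documented shape constants), beat intervals jitter with a Gaussian SD of
`hrv_pct` percent (default 2 %), and the pulsatile component is rescaled so
its peak-to-trough excursion is exactly `ac_amplitude` (default 2 units on
a 100-unit baseline — a 2 % perfusion ratio, typical of finger PPG).
Respiratory baseline drift defaults to 0.5 units at 0.25 Hz. Additive white
noise is calibrated against the pulsatile power: `noise_snr_db = -10`
(noise power ten times the AC power) corresponds to roughly 0 dB *in-band*
after the 0.5–5 Hz filter, since the band keeps about a tenth of white
noise power at 100 Hz sampling — that level is what the tests use as the
"corrupted" condition. Optional motion-artifact bursts add 0.5-s
band-limited transients at five times the AC amplitude.

Annotations (true peak positions refined to the local maxima of the
noiseless signal, per-beat intervals, the designed AC/DC ratio) come back
with the record, so recovery can be scored without circularity.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: wave-shape variability between subjects, sensor
coupling changes during rotation, colored physiological noise, arrhythmia,
and motion artifacts correlated with the pulse. Validation here shows the
pipeline recovers known truth under controlled corruption, not field
accuracy. Relatedly, the FoM reliably separates clean from clearly
corrupted sessions (the tests demand a perfect 10/10 sign test at the
-10 dB condition) but does not grade *depth* of corruption once
periodicity is destroyed, and near-threshold noise levels (broadband 0 dB,
i.e. ≈ +10 dB in band) sit at its discrimination limit — there the
session-relative normalization makes the comparison a coin flip.

## Hardware budget calculators

The `design_calc` functions are exact closed forms for the analog
front-end arithmetic: LED ON time as the sum of ADC sampling window, TIA
settling, LED/PD setup and damping margin (30 + 20 + 10 + 10 = 70 µs);
duty cycle as ON time × firing rate (0.7 % at 100 Hz); TIA settling as a
multiple of the feedback RC constant (8 × 2.5 µs = 20 µs); effective
signal-chain bandwidth as corner × ADC rate × sampling window
(100 Hz × 2.5 kHz × 30 µs = 7.5 Hz, a 25 % margin over the 6 Hz phase
-distortion floor); and the module current budget with battery life
(594.5 µA total from the packaged module list; 22 mAh / 0.5945 mA ≈ 37 h,
comfortably above a 30 h continuous-acquisition target).

One equation deserves its footnote: the TIA compensation capacitor. The
form CF = Ci/(2π·RF·UGB) sometimes quoted is dimensionally not a
capacitance (it evaluates to ~3e-24 at the 1 MΩ operating point); the
stability form √(Ci/(2π·RF·UGB)) is consistent and lands at ≈1.8 pF
(1 MΩ) and ≈17.8 pF (10 kΩ), bracketing the practical 2.5–20 pF
adjustment range. `tia_comp_cap()` implements both modes — the default is
the stability form and the literal mode is reported verbatim with a note,
with no silent correction. The packaged LED average current (179 µA) is
likewise an empirical input: the bare product of duty cycle and drive
currents underestimates the effective ON window, so the calculator never
derives it.

## Problem sizes used by the checks

The package's own verification runs at desk scale, chosen so the whole
suite completes in minutes on one core: 1e6 draws for sampling-moment
checks, 1e5 photons for transmission and symmetry checks on a 90° grid,
60-s synthetic records at 100 Hz for the signal path, ten seeded sessions
for ordering properties, and 100 seeded fixtures for formula-fidelity
oracles. Production sweeps at the 30° grid and larger photon counts use
the same code paths with different arguments.

## Known limitations

* Absolute traversal fractions depend on the optical-coefficient table;
  the packaged table is a labelled literature default, not a calibrated
  measurement set.
* The finger is a straight cylinder: no curvature of skin under ring
  pressure, no vein pulsation, no anatomical individualization.
* The SNR definition is kept literal and is NaN for raw segments with
  appreciable DC — it is reported for completeness, not used in the FoM.
* FoM magnitudes are session-relative by construction; only orderings are
  meaningful.
* Polarization, fluorescence, and time-resolved transport are out of
  scope, as are device firmware, BLE and accelerometer-based motion
  cancellation.
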