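# ringppg

Design toolkit for rotation-robust photoplethysmography (PPG) sensing in
smart rings.

A ring rotates on the finger during wear, so the LED and photodiode (PD)
keep sampling different tissue paths and signal quality swings with
position. `ringppg` implements the computational side of choosing an
LED–PD angular layout that stays informative under rotation, plus the
signal-quality and heart-rate machinery needed to evaluate such a layout,
and the timing/power arithmetic of the analog front end.

For whom: biomedical-optics and wearable-sensing engineers exploring
reflective PPG geometries, and signal-processing folks who need a seeded,
ground-truthed synthetic PPG substrate for pipeline tests.

## What is inside

* **Photon transport** (`run_simulation`) — weighted Monte Carlo in a
  multilayer cylindrical finger model (19.2 mm diameter: epidermis,
  dermis, a 16 mm microcirculation core with vessels and bone). Exponential
  free paths, Henyey–Greenstein scattering with anisotropy *g*,
  implicit-capture absorption, Russian roulette, unpolarized Fresnel
  handling at index mismatches. The figure of interest per layout is the
  *microcirculation traversal fraction* — the share of detected light that
  crossed the capillary-rich core, the assumed carrier of the pulsatile
  signal.
* **Layout sweep** (`sweep_layouts`, `aggregate_by_angle`, `rank_angles`)
  — score every (LED, PD) cell on an angular grid, pool cells sharing the
  LED–PD angle Δ = (PD − LED) mod 360 (rotation maps a layout onto exactly
  those cells), rank angles by mean fraction with dispersion tie-breaks.
* **Signal quality** (`sqi_session`, `compute_fom`) — per 6-s segment:
  pulse amplitude AC, static level DC, perfusion index PI = AC/DC, a
  literal in-band SNR, spectral skewness/kurtosis sums, and autocorrelation
  periodicity SDs; combined per segment as

  FoM = (PI · AC · S_PSD · K_PSD) / (STD_periods · STD_peaks)

  after min–max normalization across the session.
* **Heart rate** (`estimate_hr`, `hr_series`, `score_against_reference`) —
  0.5–8 Hz zero-phase band-pass, adaptive-threshold systolic peak
  detection (rolling 90th-percentile envelope × 0.5, 0.25 s refractory),
  HR = 60 / mean inter-beat interval, MAE scoring against a reference.
* **Synthetic PPG** (`synth_ppg`) — seeded two-Gaussian beat trains with
  known HR, jitter, perfusion ratio, drift, calibrated noise and artifact
  bursts, returned with ground-truth annotations.
* **Design calculators** (`duty_cycle`, `led_on_budget`,
  `tia_settling_min`, `tia_comp_cap`, `effective_bandwidth`,
  `current_budget`) — exact closed forms for the front-end timing and the
  module current budget.

A thin command-line wrapper over these functions ships in
`inst/cli/ringppg.R` (subcommands `simulate`, `sweep`, `sqi`, `hr`,
`synth`, `budget`).

## Worked example

```r
library(ringppg)

# a minute of synthetic PPG at 100 Hz, 72 bpm, with known ground truth
g <- synth_ppg(fs = 100, duration = 60, hr_bpm = 72, seed = 1)
estimate_hr(g$record)
#> peak_train: 72 peaks, HR 71.75 bpm (ok)

q <- sqi_session(g$record)       # eight indices per 6-s segment
f <- compute_fom(q)
mean(q$pi)                       # recovered perfusion index
#> [1] 0.0201                    # designed ratio was 0.0199

# one transport run on the default finger model: LED at 270 deg, PD at
# 330 deg (a 60-degree layout), infrared light, 1e5 photons
m <- build_default_finger()
run_simulation(m, ring_placement(270, 330), 940,
               transport_config(n_photons = 1e5, seed = 1))
#> mc_result: 940 nm, LED 270 deg -> PD 330 deg (delta 60)
#>   launched 100000 | detected 3.297 (n=69) | absorbed 3.881e+04 | escaped 6.119e+04
#>   micro_fraction 1.0000 (SE 0.0000), artery_fraction 0.2198
```

`micro_fraction = 1` says every detected photon crossed the
microcirculation core — typical for separated layouts, while co-located
LED/PD layouts harvest mostly shallow light (fractions of a few percent).
Ranking the packaged published reference table of per-angle traversal
means puts 60° first at all three wavelengths:

```r
head(rank_angles(reference_aggregates(550)), 3)
#>    delta mean_fraction
#> 3     60         0.878
#> 11   300         0.876
#> 4     90         0.707
```

And the front-end budget arithmetic:

```r
default_timing_budget()
#> timing_budget: LED ON 70 us (= 30 + 20 + 10 + 10), duty 0.7% @ 100 Hz
#>   fSIGEFF 7.5 Hz = fRC 100 Hz x fSP(ADC) 2500 Hz x TSAMP 30 us
current_budget(default_current_modules(), 22)
#>   total  594.5 uA (0.5945 mA);  battery 22 mAh -> lifetime 37.0 h
```

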