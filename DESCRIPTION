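Package: ringppg
Title: Rotation-Robust Ring Photoplethysmography Sensor Design Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing rotation-robust photoplethysmography (PPG)
    sensor layouts for smart rings. Provides a weighted Monte Carlo photon
    transport simulator for a multilayer cylindrical finger model with
    Henyey-Greenstein scattering and Fresnel boundary handling, scoring
    LED-photodiode angular layouts by the fraction of detected light that
    traversed the capillary-rich microcirculation layer; signal-quality
    indices (pulse amplitude, perfusion index, SNR, spectral skewness and
    kurtosis, autocorrelation periodicity) combined into a figure of merit;
    heart-rate estimation from pulse waveforms via adaptive-threshold
    systolic peak detection; a seeded synthetic PPG generator with ground
    truth annotations; and closed-form timing and power budget calculators
    for the analog front end (LED duty cycle, transimpedance amplifier
    settling and compensation, module current budget, battery life).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    zoo,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
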