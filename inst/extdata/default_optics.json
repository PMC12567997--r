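{
  "source": "literature defaults",
  "comment": "Placeholder tissue optical coefficients (per mm) assembled from standard skin-optics compendium values at 550/628/940 nm. Interior refractive indices are index-matched at 1.40 (1.39 for whole blood rounded to 1.40; 1.55 typical for cortical bone kept at 1.40 here so Fresnel physics acts only at the skin-air boundary by default). Replace with a measurement-specific table for quantitative work.",
  "optics": {
    "epidermis": {
      "550": {"mu_a": 0.35, "mu_s": 45.0, "g": 0.79, "n": 1.4},
      "628": {"mu_a": 0.15, "mu_s": 35.0, "g": 0.80, "n": 1.4},
      "940": {"mu_a": 0.05, "mu_s": 25.0, "g": 0.85, "n": 1.4}
    },
    "dermis": {
      "550": {"mu_a": 0.25, "mu_s": 25.0, "g": 0.79, "n": 1.4},
      "628": {"mu_a": 0.08, "mu_s": 20.0, "g": 0.80, "n": 1.4},
      "940": {"mu_a": 0.03, "mu_s": 15.0, "g": 0.85, "n": 1.4}
    },
    "microcirculation": {
      "550": {"mu_a": 0.45, "mu_s": 22.0, "g": 0.85, "n": 1.4},
      "628": {"mu_a": 0.10, "mu_s": 18.0, "g": 0.87, "n": 1.4},
      "940": {"mu_a": 0.06, "mu_s": 14.0, "g": 0.90, "n": 1.4}
    },
    "vessel": {
      "550": {"mu_a": 23.0, "mu_s": 70.0, "g": 0.98, "n": 1.4},
      "628": {"mu_a": 0.45, "mu_s": 80.0, "g": 0.98, "n": 1.4},
      "940": {"mu_a": 0.65, "mu_s": 60.0, "g": 0.97, "n": 1.4}
    },
    "bone": {
      "550": {"mu_a": 0.08, "mu_s": 35.0, "g": 0.90, "n": 1.4},
      "628": {"mu_a": 0.05, "mu_s": 30.0, "g": 0.90, "n": 1.4},
      "940": {"mu_a": 0.04, "mu_s": 25.0, "g": 0.90, "n": 1.4}
    }
  }
}
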