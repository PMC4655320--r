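{
  "name": "customisation_surrogate",
  "comment": "Simplified customised-centile model: a linear term-optimal-weight adjustment for maternal characteristics scaled along the fetal weight-for-GA proportionality curve. Coefficient magnitudes are illustrative defaults, not the proprietary GROW coefficients.",
  "term_ga_weeks": 40,
  "base_term_weight_g": 3480,
  "reference_height_cm": 163,
  "reference_weight_kg": 65,
  "height_g_per_cm": 7.0,
  "weight_g_per_kg": 5.5,
  "smoker_g": -160,
  "ethnicity_g": {
    "white": 0,
    "south_asian": -180,
    "black": -110,
    "other": -60
  },
  "cv": 0.127,
  "proportionality_standard": "hadlock1991_efw_ga"
}
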