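{
  "name": "biometry_reference_synthetic",
  "comment": "Synthetic median fetal biometry curves (cm) by gestational age, anchored at 4-weekly knots and interpolated with a monotone spline. Used by the cohort generator; magnitudes are typical clinical values, not a published chart.",
  "ga_knots": [16, 20, 24, 28, 32, 36, 40, 44],
  "median_cm": {
    "bpd": [3.6, 4.9, 6.2, 7.2, 8.2, 8.9, 9.5, 9.9],
    "hc":  [12.5, 17.5, 22.0, 26.0, 29.5, 32.5, 34.8, 36.2],
    "ac":  [10.5, 15.0, 19.5, 24.0, 28.0, 32.0, 35.5, 38.2],
    "fl":  [2.1, 3.3, 4.4, 5.3, 6.2, 6.9, 7.6, 8.1]
  },
  "fractional_sd_per_z": {
    "comment": "fractional change of each measure per unit of the common fetal-size factor",
    "bpd": 0.030,
    "hc": 0.030,
    "ac": 0.040,
    "fl": 0.035
  }
}
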