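{
  "comment": "Estimated-fetal-weight regression equations. Coefficients act on biometry in cm and return log10(weight in g). Transcribed from the published Hadlock regression models; verify against cited reference before clinical use.",
  "equations": {
    "hcacfl": {
      "citation": "Hadlock FP et al. Estimation of fetal weight with the use of head, body, and femur measurements. Am J Obstet Gynecol 1985;151:333-337 (model HC/AC/FL).",
      "requires": ["hc_cm", "ac_cm", "fl_cm"],
      "intercept": 1.326,
      "ac_fl": -0.00326,
      "hc": 0.0107,
      "ac": 0.0438,
      "fl": 0.158
    },
    "bpdhcacfl": {
      "citation": "Hadlock FP et al. Am J Obstet Gynecol 1985;151:333-337 (model BPD/HC/AC/FL).",
      "requires": ["bpd_cm", "hc_cm", "ac_cm", "fl_cm"],
      "intercept": 1.3596,
      "ac_fl": -0.00386,
      "bpd_ac": 0.00061,
      "hc": 0.0064,
      "ac": 0.0424,
      "fl": 0.174
    }
  }
}
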