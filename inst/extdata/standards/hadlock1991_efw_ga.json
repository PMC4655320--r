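{
  "name": "hadlock1991_efw_ga",
  "kind": "efw_for_ga",
  "working_scale": "natural",
  "citation": "Hadlock FP, Harrist RB, Martinez-Poyer J. In utero analysis of fetal growth: a sonographic weight standard. Radiology 1991;181:129-133. Transcription; verify against cited reference.",
  "ga_range": [18, 42],
  "median_log_coefficients": {
    "comment": "median weight (g) = exp(c0 + c1*ga + c2*ga^2), ga in decimal weeks",
    "c0": 0.578,
    "c1": 0.332,
    "c2": -0.00354
  },
  "sd_fraction_of_median": 0.127
}
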