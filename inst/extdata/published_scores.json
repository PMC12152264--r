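{
  "comment": "Published clinical-practice response scores (training set, N=1152) with responder classification cut-offs equal to the whole-group hazard ratio per outcome. Coefficients act on transformed covariates: disease duration enters as log base 10, sex as a male indicator. Two printed coefficients are reconciled against the fully worked patient examples: the EDSS relapse term is stored as +0.05 (a printed minus sign is inconsistent with both worked patients) and the SDMT disease-duration term as -0.15 (the tabulated value; the running text prints -0.19, which does not reproduce the worked scores).",
  "scores": {
    "EDSS": {
      "intercept": -1.23,
      "coefficients": {"age": 0.01, "edss": 0.08, "relapses_2y": 0.05},
      "overall_hr": 0.79
    },
    "9HPT": {
      "intercept": -0.39,
      "coefficients": {"age": 0.005},
      "overall_hr": 0.86
    },
    "T25FW": {
      "intercept": -0.58,
      "coefficients": {"age": 0.01, "edss": 0.11,
                       "log10_disease_duration": -0.19,
                       "relapses_2y": -0.09},
      "overall_hr": 0.95
    },
    "SDMT": {
      "intercept": -0.56,
      "coefficients": {"edss": 0.10, "male": 0.34,
                       "log10_disease_duration": -0.15},
      "overall_hr": 0.75
    }
  }
}
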