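{
  "feature": "T_amp_I_mV",
  "op": "le",
  "threshold": 0.055,
  "left": {
    "feature": "QRS_ppk_aVF_mV",
    "op": "gt",
    "threshold": 0.178,
    "left": {
      "class": "positive",
      "p": 1,
      "phenotype": "repolarization_lvh"
    },
    "right": {
      "class": "negative",
      "p": 0
    }
  },
  "right": {
    "feature": "QRS_ppk_aVL_mV",
    "op": "gt",
    "threshold": 1.235,
    "left": {
      "class": "positive",
      "p": 1,
      "phenotype": "voltage_lvh"
    },
    "right": {
      "class": "negative",
      "p": 0
    }
  }
}
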