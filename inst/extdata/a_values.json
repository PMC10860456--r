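{
  "target_a": {
    "prostate": -25,
    "lung": -20,
    "brain_met": -10,
    "spine_met": -20
  },
  "oar_a": {
    "rectum": 8.33,
    "bladder": 2,
    "normal_lung": 1.15,
    "spinal_cord": 20,
    "normal_brain": 4
  }
}
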