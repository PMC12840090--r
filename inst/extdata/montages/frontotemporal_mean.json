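[
 {
  "name": "Fp2T8",
  "hemisphere": "right",
  "weights": {
   "Fp2": 0.5,
   "T8": 0.5
  }
 },
 {
  "name": "Fp1T7",
  "hemisphere": "left",
  "weights": {
   "Fp1": 0.5,
   "T7": 0.5
  }
 }
]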