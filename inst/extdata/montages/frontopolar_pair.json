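[
 {
  "name": "Fp2",
  "hemisphere": "right",
  "weights": {
   "Fp2": 1
  }
 },
 {
  "name": "Fp1",
  "hemisphere": "left",
  "weights": {
   "Fp1": 1
  }
 }
]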