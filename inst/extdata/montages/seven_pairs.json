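[
 {
  "name": "Fp2",
  "hemisphere": "right",
  "weights": {
   "Fp2": 1
  }
 },
 {
  "name": "F4",
  "hemisphere": "right",
  "weights": {
   "F4": 1
  }
 },
 {
  "name": "C4",
  "hemisphere": "right",
  "weights": {
   "C4": 1
  }
 },
 {
  "name": "O2",
  "hemisphere": "right",
  "weights": {
   "O2": 1
  }
 },
 {
  "name": "F8",
  "hemisphere": "right",
  "weights": {
   "F8": 1
  }
 },
 {
  "name": "T8",
  "hemisphere": "right",
  "weights": {
   "T8": 1
  }
 },
 {
  "name": "P8",
  "hemisphere": "right",
  "weights": {
   "P8": 1
  }
 },
 {
  "name": "Fp1",
  "hemisphere": "left",
  "weights": {
   "Fp1": 1
  }
 },
 {
  "name": "F3",
  "hemisphere": "left",
  "weights": {
   "F3": 1
  }
 },
 {
  "name": "C3",
  "hemisphere": "left",
  "weights": {
   "C3": 1
  }
 },
 {
  "name": "O1",
  "hemisphere": "left",
  "weights": {
   "O1": 1
  }
 },
 {
  "name": "F7",
  "hemisphere": "left",
  "weights": {
   "F7": 1
  }
 },
 {
  "name": "T7",
  "hemisphere": "left",
  "weights": {
   "T7": 1
  }
 },
 {
  "name": "P7",
  "hemisphere": "left",
  "weights": {
   "P7": 1
  }
 }
]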