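[
 {
  "name": "R01",
  "hemisphere": "right",
  "weights": {
   "R01": 1
  }
 },
 {
  "name": "R02",
  "hemisphere": "right",
  "weights": {
   "R02": 1
  }
 },
 {
  "name": "R03",
  "hemisphere": "right",
  "weights": {
   "R03": 1
  }
 },
 {
  "name": "R04",
  "hemisphere": "right",
  "weights": {
   "R04": 1
  }
 },
 {
  "name": "R05",
  "hemisphere": "right",
  "weights": {
   "R05": 1
  }
 },
 {
  "name": "R06",
  "hemisphere": "right",
  "weights": {
   "R06": 1
  }
 },
 {
  "name": "R07",
  "hemisphere": "right",
  "weights": {
   "R07": 1
  }
 },
 {
  "name": "R08",
  "hemisphere": "right",
  "weights": {
   "R08": 1
  }
 },
 {
  "name": "R09",
  "hemisphere": "right",
  "weights": {
   "R09": 1
  }
 },
 {
  "name": "R10",
  "hemisphere": "right",
  "weights": {
   "R10": 1
  }
 },
 {
  "name": "R11",
  "hemisphere": "right",
  "weights": {
   "R11": 1
  }
 },
 {
  "name": "R12",
  "hemisphere": "right",
  "weights": {
   "R12": 1
  }
 },
 {
  "name": "R13",
  "hemisphere": "right",
  "weights": {
   "R13": 1
  }
 },
 {
  "name": "R14",
  "hemisphere": "right",
  "weights": {
   "R14": 1
  }
 },
 {
  "name": "R15",
  "hemisphere": "right",
  "weights": {
   "R15": 1
  }
 },
 {
  "name": "R16",
  "hemisphere": "right",
  "weights": {
   "R16": 1
  }
 },
 {
  "name": "L01",
  "hemisphere": "left",
  "weights": {
   "L01": 1
  }
 },
 {
  "name": "L02",
  "hemisphere": "left",
  "weights": {
   "L02": 1
  }
 },
 {
  "name": "L03",
  "hemisphere": "left",
  "weights": {
   "L03": 1
  }
 },
 {
  "name": "L04",
  "hemisphere": "left",
  "weights": {
   "L04": 1
  }
 },
 {
  "name": "L05",
  "hemisphere": "left",
  "weights": {
   "L05": 1
  }
 },
 {
  "name": "L06",
  "hemisphere": "left",
  "weights": {
   "L06": 1
  }
 },
 {
  "name": "L07",
  "hemisphere": "left",
  "weights": {
   "L07": 1
  }
 },
 {
  "name": "L08",
  "hemisphere": "left",
  "weights": {
   "L08": 1
  }
 },
 {
  "name": "L09",
  "hemisphere": "left",
  "weights": {
   "L09": 1
  }
 },
 {
  "name": "L10",
  "hemisphere": "left",
  "weights": {
   "L10": 1
  }
 },
 {
  "name": "L11",
  "hemisphere": "left",
  "weights": {
   "L11": 1
  }
 },
 {
  "name": "L12",
  "hemisphere": "left",
  "weights": {
   "L12": 1
  }
 },
 {
  "name": "L13",
  "hemisphere": "left",
  "weights": {
   "L13": 1
  }
 },
 {
  "name": "L14",
  "hemisphere": "left",
  "weights": {
   "L14": 1
  }
 },
 {
  "name": "L15",
  "hemisphere": "left",
  "weights": {
   "L15": 1
  }
 },
 {
  "name": "L16",
  "hemisphere": "left",
  "weights": {
   "L16": 1
  }
 }
]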