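[
 {
  "compound_id": "demo01",
  "species": {
   "state0": {
    "MolLogP": 10.37,
    "TPSA": 51.377,
    "PEOE_VSA6": 3.94,
    "NHOHCount": 41.942
   },
   "state1": {
    "MolLogP": 27.986,
    "TPSA": 2.756,
    "PEOE_VSA6": 39.61,
    "NHOHCount": 1.075
   }
  },
  "pka_values": [
   4.59
  ],
  "site_types": [
   "acidic"
  ],
  "logd_by_ph": {
   "2.7": 1.168,
   "7": -0.651
  }
 },
 {
  "compound_id": "demo02",
  "species": {
   "state0": {
    "MolLogP": 65.802,
    "TPSA": 8.152,
    "PEOE_VSA6": 16.306,
    "NHOHCount": 49.45
   },
   "state1": {
    "MolLogP": 75.712,
    "TPSA": 45.322,
    "PEOE_VSA6": 30.528,
    "NHOHCount": 78.053
   },
   "state2": {
    "MolLogP": 1.82,
    "TPSA": 68.394,
    "PEOE_VSA6": 21.748,
    "NHOHCount": 9.829
   }
  },
  "pka_values": [
   2.73,
   5.4
  ],
  "site_types": [
   "acidic",
   "acidic"
  ],
  "logd_by_ph": {
   "2.7": -0.411,
   "7": 0.542
  }
 },
 {
  "compound_id": "demo03",
  "species": {
   "state0": {
    "MolLogP": 64.922,
    "TPSA": 12.82,
    "PEOE_VSA6": 45.691,
    "NHOHCount": 50.391
   }
  },
  "pka_values": [],
  "site_types": [],
  "logd_by_ph": {
   "2.7": 0.862,
   "7": 1.739
  }
 },
 {
  "compound_id": "demo04",
  "species": {
   "state0": {
    "MolLogP": 2.887,
    "TPSA": 14.889,
    "PEOE_VSA6": 53.793,
    "NHOHCount": 33.063
   },
   "state1": {
    "MolLogP": 23.76,
    "TPSA": 46.016,
    "PEOE_VSA6": 35.161,
    "NHOHCount": 22.581
   }
  },
  "pka_values": [
   2.5
  ],
  "site_types": [
   "acidic"
  ],
  "logd_by_ph": {
   "2.7": 2.972,
   "7": 2.495
  }
 },
 {
  "compound_id": "demo05",
  "species": {
   "state0": {
    "MolLogP": 41.066,
    "TPSA": 69.761,
    "PEOE_VSA6": 57.815,
    "NHOHCount": 21.611
   },
   "state1": {
    "MolLogP": 78.374,
    "TPSA": 7.681,
    "PEOE_VSA6": 32.286,
    "NHOHCount": 60.086
   },
   "state2": {
    "MolLogP": 10.463,
    "TPSA": 38.095,
    "PEOE_VSA6": 1.215,
    "NHOHCount": 52.794
   }
  },
  "pka_values": [
   3.95,
   6.6
  ],
  "site_types": [
   "acidic",
   "acidic"
  ],
  "logd_by_ph": {
   "2.7": 2.823,
   "7": 1.865
  }
 }
]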