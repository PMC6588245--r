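{
  "note": "Example pose-matching weights for the synthetic walker rig. Weighting follows the qualitative rule used for whole-body marker sets: full weight on the analysed heel and on markers standing in for bony landmarks, reduced weight on markers standing in for soft-tissue placements. This is an illustration, not a reproduction of any lab's configuration.",
  "default": 0.5,
  "weights": {
    "RHEE": 1.0,
    "AUX1": 1.0,
    "AUX2": 0.8,
    "AUX3": 0.8,
    "AUX4": 0.3,
    "AUX5": 0.3,
    "AUX6": 0.5,
    "AUX7": 0.5
  }
}
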