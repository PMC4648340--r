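{
  "enable_fpj": false,
  "enable_sam": false,
  "thresholds": {
    "tiv": {"caution": 30, "concern": 50, "direction": "high"},
    "decay": {"caution": 20, "concern": 40, "direction": "high"},
    "angle_diff": {"caution": 20, "concern": 40, "direction": "high"},
    "flicker": {"caution": 10, "concern": 25, "direction": "high"},
    "mcnr": {"caution": 8, "concern": 4, "direction": "low"},
    "mmr": {"caution": 6, "concern": 3, "direction": "low"},
    "zmv": {"caution": 0.1, "concern": 0.3, "direction": "high"},
    "saturated_fraction": {"caution": 0.001, "concern": 0.01, "direction": "high"},
    "colour_spread": {"caution": 0.15, "concern": 0.3, "direction": "high"}
  }
}
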