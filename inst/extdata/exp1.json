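{
  "cohort": {
    "experiment": "exp1",
    "n_flights": 10,
    "speed_mean": 55,
    "speed_sd": 5,
    "noise_sd": 0.25,
    "quantize": true,
    "seed": 7
  },
  "controller": {
    "k_gain": 2.5,
    "c_star": 0.5,
    "safety_mode": true
  }
}
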