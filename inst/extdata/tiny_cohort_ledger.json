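{
  "profile": "tiny",
  "n": 50,
  "seed": 104729,
  "obs_total_rows_1_5": [13, 21, 20, 14, 16],
  "obs_dietary_rows_1_5": [9, 16, 15, 12, 13],
  "obs_lifestyle_rows_1_5": [4, 5, 5, 2, 3],
  "n_high_risk": 16,
  "n_death": 11
}
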