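{
  "study_id": "study4_rating",
  "scale": {
    "name": "11-point",
    "min_score": 0,
    "max_score": 10
  },
  "willingness_mode": "rating",
  "formulations": ["PSP TMT", "PSP LQD"]
}
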