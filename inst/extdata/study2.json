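{
  "study_id": "study2",
  "scale": {
    "name": "5-point hedonic",
    "min_score": 1,
    "max_score": 5
  },
  "willingness_mode": "binary",
  "formulations": ["TRM TMT", "TRM LQD"]
}
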