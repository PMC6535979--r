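{
  "score_term": "Alvarado score",
  "flagged": true,
  "bands": [
    {"upper": 4, "upper_incl": false, "action": {"procedure": "CT Abdomen"}, "polarity": "not_recommend"},
    {"lower": 4, "upper": 6, "action": {"procedure": "CT abdomen"}, "polarity": "recommend"},
    {"lower": 6, "lower_incl": false, "action": {"procedure": "CT Abdomen"}, "polarity": "not_recommend"}
  ]
}
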