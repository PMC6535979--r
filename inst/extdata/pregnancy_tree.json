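{
  "condition": {"term": "Pregnant"},
  "yes": {"action": {"procedure": "VQ SPECT"}, "polarity": "recommend"},
  "no": {"action": {"procedure": "CTPA"}, "polarity": "recommend"}
}
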