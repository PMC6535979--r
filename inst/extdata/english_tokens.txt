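# Common-English tokens used to classify unmapped terms as ordinary
# English phrases rather than missing clinical terms.
new
feature
features
suitable
candidate
vehicle
rollover
time-of-flight
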