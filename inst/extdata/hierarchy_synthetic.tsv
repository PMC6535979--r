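child	parent
900000110	900000100
900000120	900000100
900000111	900000110
900000112	900000110
900000113	900000110
900000114	900000110
900000115	900000110
900000121	900000120
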