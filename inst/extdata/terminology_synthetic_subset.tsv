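term	concept_ids	match_type
Suspected PE	417113001	precoordinated
VQ SPECT	900000121	precoordinated
CTPA	900000113	precoordinated
CT abdomen	900000112	precoordinated
CT chest	900000111	precoordinated
X-ray knee	900000115	precoordinated
Pregnant	900000201	precoordinated
Pulmonary nodule on chest CT	900000301;900000111	postcoordinated
Nodule size	900000302	precoordinated
High risk	900000303	precoordinated
Low risk	900000304	precoordinated
Low-dose CT	900000114	precoordinated
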