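# Named clinical scores and rules deliberately absent from the packaged
# terminology subset (they have no standard-ontology concept).
AIR score
Alvarado score
Canadian CT Head Rule
Canadian Cervical Spine Rule
New Orleans/Charity head trauma rule
NEXUS head trauma rule
MRI shoulder with dedicated metal suppression protocol
O2 saturation on room air
OPTIMAP score
Revised Geneva score
SCORE score
Simplified Motor Score
STONE score
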