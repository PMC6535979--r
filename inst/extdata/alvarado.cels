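# Score-based statement set: Alvarado score for suspected appendicitis.
# The asterisk marks a term known to lack a terminology mapping.
If [Alvarado score* >=4] And [Alvarado score* <=6] Then [CT abdomen]
If [Alvarado score* <4] Then Not [CT Abdomen]
If [Alvarado score* >6] Then Not [CT Abdomen]
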