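protein1	protein2	combined_score
A	B	700
B	A	700
B	C	150
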