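gene	metabolite_id	monoisotopic_mass
GENEA	SMET00001	175.0957
GENEB	SMET00001	175.0957
GENEA	SMET00002	132.0535
GENEB	SMET00003	300.1250
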