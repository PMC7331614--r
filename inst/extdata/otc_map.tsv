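gene	metabolite_id	monoisotopic_mass
OTC	HMDB0000904	175.0957
OTC	HMDB0000214	132.0535
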