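code	display	parents
at0006	Nasal canula
at0007	Face mask
at0101	Suspicion
at0102	Certainty
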