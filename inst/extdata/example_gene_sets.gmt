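stromal_program		g00001	g00017
immune_program		g00009	g00020
null_set_01		g00014	g00006	g00011
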