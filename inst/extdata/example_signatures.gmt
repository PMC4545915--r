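stromal_signature		g00001	g00017
immune_signature		g00009	g00020
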