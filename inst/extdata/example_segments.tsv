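chrom	start	end	log2_ratio
chr1	0	5e+06	0.35
chr1	5e+06	9e+06	0.05
chr1	9e+06	2e+07	-0.4
chr2	0	2e+06	0
chr2	2e+06	8e+06	0.25
chr2	8e+06	1.5e+07	-0.1
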