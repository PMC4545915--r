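gene	mutated_cell_lines	n_cell_lines	tumour_frequency
TP53	40	50	0.35
PTEN	12	50	0.05
NF1	10	50	0.04
PTPRD	9	50	0.04
PIK3CA	17	50	0.34
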