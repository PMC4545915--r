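sample_id	source	er_status	subtype
tumour_001	tumour	positive	luminal
tumour_002	tumour	negative	basal
tumour_003	tumour	negative	basal
tumour_004	tumour	negative	basal
tumour_005	tumour	positive	luminal
tumour_006	tumour	positive	luminal
tumour_007	tumour	positive	luminal
tumour_008	tumour	negative	basal
cellline_01	cell_line	negative	basal
cellline_02	cell_line	negative	basal
cellline_03	cell_line	positive	luminal
cellline_04	cell_line	positive	luminal
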