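# period_h=24 label=TOC1_protein_synthetic units=molecules_per_cell light_regime=12L:12D
time_h,value
4,85.0
8,112.0
12,98.0
16,64.0
20,26.0
24,38.0
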