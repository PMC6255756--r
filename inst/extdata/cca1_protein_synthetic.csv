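# period_h=24 label=CCA1_protein_synthetic units=molecules_per_cell light_regime=12L:12D
time_h,value
4,276.2
8,383.1
12,356.4
16,231.7
20,106.9
24,102.5
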