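# period_h=24 label=TOC1_degradation_synthetic units=per_h light_regime=12L:12D
time_h,value
4,0.130
8,0.115
12,0.180
16,0.240
20,0.280
24,0.160
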