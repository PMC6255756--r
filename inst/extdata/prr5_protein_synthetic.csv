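# period_h=24 label=PRR5_protein_synthetic units=normalized light_regime=12L:12D
time_h,value
0,0.0280
2,0.0500
4,0.1000
6,0.3000
8,0.6000
10,0.9000
12,1.0000
14,0.9000
16,0.7000
18,0.4500
20,0.3000
22,0.0485
24,0.0280
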