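# period_h=24 label=PRR7_protein_synthetic units=normalized light_regime=12L:12D
time_h,value
0,0.0650
2,0.0600
4,0.1700
6,0.4500
8,0.8200
10,1.0000
12,0.9600
14,0.7500
16,0.5400
18,0.3500
20,0.1800
22,0.0420
24,0.0650
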