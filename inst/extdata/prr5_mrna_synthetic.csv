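# period_h=24 label=PRR5_mRNA_synthetic units=normalized light_regime=12L:12D
time_h,value
0,0.0800
2,0.1000
4,0.2500
6,0.5500
8,0.8500
10,1.0000
12,0.9000
14,0.6500
16,0.4000
18,0.2200
20,0.1200
22,0.0800
24,0.0800
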