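# period_h=24 label=PRR7_mRNA_synthetic units=normalized light_regime=12L:12D
time_h,value
0,0.1000
2,0.2000
4,0.6000
6,0.9500
8,1.0000
10,0.8500
12,0.6000
14,0.4000
16,0.2500
18,0.1500
20,0.1000
22,0.0800
24,0.1000
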