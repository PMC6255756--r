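time_h,rate_per_h,sd_per_h,source
4,0.22,,synthetic_chase
12,0.18,,synthetic_chase
18,0.45,0.11,synthetic_chase
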