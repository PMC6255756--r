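time_h,rate_per_h,sd_per_h,source
12,0.14,,synthetic_chase
19,0.45,,synthetic_chase
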