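time_h,rate_per_h,sd_per_h,source
9.4,0.16,,synthetic_chase
12.4,0.18,,synthetic_chase
15.4,0.32,,synthetic_chase
18.4,0.50,,synthetic_chase
20.4,0.28,,synthetic_chase
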