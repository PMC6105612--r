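distance_cm,setting_pct,power_mw_cm2
20,100,25.2
35,100,4.7
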