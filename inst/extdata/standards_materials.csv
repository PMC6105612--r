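standard,thickness_in,concentration_ppt
1,0.02,0.5
2,0.04,0.5
3,0.08,0.5
4,0.02,2.7
5,0.04,2.7
6,0.08,2.7
7,0.02,8.1
8,0.04,8.1
9,0.08,8.1
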