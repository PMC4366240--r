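>p53_halfsite_synthetic
50	50	50	0	50	50	0	0	0	0
0	0	0	100	0	0	0	50	50	50
50	50	50	0	0	0	100	0	0	0
0	0	0	0	50	50	0	50	50	50
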