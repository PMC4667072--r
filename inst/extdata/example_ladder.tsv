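copies	intensity
100000	100
1000000	1000
10000000	10000
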