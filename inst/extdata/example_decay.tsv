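time	signal
0	100
12	69.6532
24	48.5156
36	33.7927
48	23.5377
60	16.3947
72	11.4195
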