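time_s,B_T
0,0.001
42,0.001
57,1.0
60,9.4
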