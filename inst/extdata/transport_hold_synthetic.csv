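time_s,B_T
0,0.001
60,0.001
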