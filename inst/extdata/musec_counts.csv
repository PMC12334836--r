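stage,arm,successes,total
1,control,12,97
1,treatment,27,101
2,control,21,134
2,treatment,42,143
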