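# two coupled feedback loops: module {x1,x2} drives module {x3,x4} through x2
targets, factors
x1, x2
x2, x1
x3, x2 & x4
x4, x3
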