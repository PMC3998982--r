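exploitation,keystone,structuring,other
fished,104,78,2184
none,6,5,116
light,14,1,127
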