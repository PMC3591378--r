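toy two-population export
locA
locB
Pop
a1 , 0101 0102
a2 , 0102 0000
Pop
b1 , 0202 0101
b2 , 0202 0202
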