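individual_id,length_mm,mass_g,snp1,snp2,mt
f1,65,3.1,A/C,G/G,H1
f2,70,3.9,C/A,-,H2
f3,62,2.8,A/A,G/T,H1
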