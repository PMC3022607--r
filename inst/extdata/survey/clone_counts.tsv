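genotype	total_clones
A	14
B	9
C1	14
C2	13
D	12
E	10
F	16
G	14
H	NA
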