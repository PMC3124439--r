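label	n_genes
A	19
B	24
C	16
D	36
E	50
F	36
G	26
H	26
X	17
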