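gene_a	gene_b
G0003	G0017
G0008	G0021
G0011	G0002
G0014	G0029
G0020	G0005
G0026	G0013
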