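gene_id	c1	c2	c3
G1	1	2	3
G2	2	2	2
G3	0	1	5
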