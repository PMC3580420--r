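#geneA	geneB	evidence	score
a	b	ppi	0.9
b	c	kegg	0.8
c	d	ppi,kegg	0.7
d	a	mrna_coexpr	0.6
a	c	complex	0.5
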