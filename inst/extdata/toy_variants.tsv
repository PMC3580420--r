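chrom	pos	ref	alt	gene	dna_depth	dna_alt_depth	rna_depth	rna_alt_depth	damaging	common_polymorphism
chr1	100	A	T	geneA	40	20	30	15	TRUE	FALSE
chr1	200	C	G	geneA	40	20	30	15	TRUE	TRUE
chr1	300	G	A	geneB	30	12	25	12	TRUE	FALSE
chr1	400	T	C	geneC	50	5	40	20	TRUE	FALSE
chr1	500	A	G	geneC	50	25	40	20	TRUE	FALSE
chr1	600	C	T	geneD	60	30	50	25	TRUE	FALSE
chr1	700	G	C	geneE	25	10	20	10	TRUE	FALSE
chr1	800	T	A	geneF	40	20	30	15	FALSE	FALSE
chr1	900	A	C	geneG	40	20	30	15	TRUE	TRUE
chr1	1000	C	A	geneH	40	20	30	15	FALSE	TRUE
chr1	1100	G	T	geneB	45	18	35	17	TRUE	FALSE
chr1	1200	T	G	geneI	30	3	25	12	TRUE	FALSE
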