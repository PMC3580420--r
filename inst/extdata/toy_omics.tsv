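gene	line	copy_number	rpkm	protein
g01	L1	1	2	1
g01	L2	2	5	2
g01	L3	4	9	3
g02	L1	1	3	NA
g02	L2	2	6	NA
g02	L3	4	12	NA
g03	L1	1	2	1
g03	L2	2	9	2
g03	L3	4	5	3
g04	L1	2	2	1
g04	L2	2	5	2
g04	L3	2	9	3
g05	L1	1	0.2	1
g05	L2	2	0.5	2
g05	L3	4	0.9	3
g06	L1	4	9	3
g06	L2	2	5	2
g06	L3	1	2	1
g07	L1	1	9	2
g07	L2	2	5	3
g07	L3	4	2	4
g08	L1	1	2	3
g08	L2	2	5	1
g08	L3	4	9	2
g09	L1	1	1.5	2
g09	L2	3	4	6
g09	L3	8	20	30
g10	L1	1	5	1
g10	L2	2	5	2
g10	L3	4	5	3
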