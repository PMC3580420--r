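S1	first toy set	g1	g2	g3
S2	second toy set	g3	g4	g5	g6
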