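analysis	row_context	outcome	count
g_to_a	CG	G>A	41377
g_to_a	CG	G>B	633155
g_to_a	DG	G>A	184227
g_to_a	DG	G>B	3835559
c_to_t	CG	C>T	41607
c_to_t	CG	C>V	633520
c_to_t	CH	C>T	183849
c_to_t	CH	C>V	3838041
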