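id	junction	homology_bp	note
J1617a	+16:+17	2	MMBIR
J1617b	+17:+16	0	TINS (6 nucleotide inversion)
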