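id	junction	homology_bp	note
J13a	+13.1:-13.2	5	MMBIR
J13b	-13.2:+13.3	0	NHEJ
J13c	+13.3:+13.1	23	Alu-Alu homology
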