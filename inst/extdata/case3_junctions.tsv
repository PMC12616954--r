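id	junction	homology_bp	note
J20a	-20.1:-20.5	38	LTR homology
J20b	+20.2:-20.1	4	MMBIR
J20c	-20.3:-20.4	0	NHEJ
J20d	-20.4:+20.2	2	MMBIR
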