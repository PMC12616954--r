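# Case 2: linked duplications on chromosomes 16 and 17 (GRCh38)
id	chrom	start	end	gain	role	note
16	chr16	77258535	79267342	1	duplicated	homologous origin; MMBIR
17	chr17	69913550	70477256	1	duplicated	homologous origin; TINS (6 nucleotide inversion)
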