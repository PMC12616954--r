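# Case 1: interspersed duplications on chromosome 13 (GRCh38)
id	chrom	start	end	gain	role	note
13.1	chr13	22222612	22545849	1	duplicated	heterologous origin; MMBIR
13.2	chr13	23312551	23312698	1	duplicated	heterologous origin; NHEJ; inverted in the duplicated copy
13.3	chr13	23609688	23854091	1	duplicated	homologous origin; Alu-Alu homology
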