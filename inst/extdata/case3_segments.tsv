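# Case 3: chromoanasynthesis on chromosome 20 (GRCh38); 20.4 is triplicated
id	chrom	start	end	gain	role	note
20.1	chr20	9153480	9780418	1	duplicated	heterologous origin; LTR homology
20.2	chr20	12115100	12319713	1	duplicated	heterologous origin; MMBIR
20.3	chr20	12350710	12564055	1	duplicated	origin uncertain (?homologous); NHEJ
20.4	chr20	12564056	12626497	2	duplicated	heterologous origin; MMBIR
20.5	chr20	12626498	12657715	1	duplicated	origin uncertain (?homologous)
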