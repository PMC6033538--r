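gene_id	chrom	start	end	strand	ph	n_tags	fdr	replicates	antisera
E01	chr1	100	150	+	8	12	0.001	r1;r2;r3	A;B
E01	chr1	400	450	+	5	7	0.001	r1;r2;r3	A;B
E02	chr1	100	160	+	12	14	0.001	r1;r2	A;B
E03	chr1	100	140	+	7	9	0.001	r1;r2;r3;r4	A
E04	chr1	100	130	+	6	8	0.001	r1;r2	A
E04	chr1	120	170	+	4	6	0.001	r3;r4	B
E05	chr1	200	230	+	9	11	0.001	r2;r3;r5	B
E06	chr1	100	135	+	20	25	0.001	r1;r2;r3;r4;r5	A;B
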