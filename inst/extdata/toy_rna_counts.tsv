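gene_id	WT_1	WT_2	KO_1	KO_2
E01	10	10	10	10
E02	4	4	1	1
E03	1	1	4	4
E04	3	3	3	3
E05	2	2	2	2
E06	0	8	1	1
E07	100	100	90	90
E08	5	1	1	1
E09	50	50	50	50
E10	6	6	0	0
E11	0	0	0	0
E12	8	8	8	8
fill	999811	999807	999830	999830
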