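gene_id	WT_1	WT_2	KO_1	KO_2
E01	2	2	2	2
E02	1.5	0.8	1.2	0.9
E03	0.5	0.5	2	3
E04	5	5	5	5
E05	0	0	0	0
E06	1	1	1	1
E07	10	10	10	10
E08	2	2	2	2
E09	1.1	1.1	0	0
E10	0	2	2	0
E11	0	0	0	0
E12	0.9	1.2	1.3	1.4
fill	999976.0	999974.4	999973.5	999974.7
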