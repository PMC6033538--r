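gene_id	length
E01	1000
E02	1000
E03	1000
E04	1000
E05	1000
E06	1000
E07	1000
E08	1000
E09	1000
E10	1000
E11	1000
E12	1000
fill	1000
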