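sample	genotype	replicate	assay
WT_1	WT	1	rnaseq
WT_2	WT	2	rnaseq
KO_1	KO	1	rnaseq
KO_2	KO	2	rnaseq
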