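sample	genotype	replicate	assay
WT_1	WT	1	riboprof
WT_2	WT	2	riboprof
KO_1	KO	1	riboprof
KO_2	KO	2	riboprof
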