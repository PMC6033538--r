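Synthetic toy fixtures (hand-written, not derived from any experiment).

toy_rna_counts.tsv / toy_rp_counts.tsv: 12-gene count tables (2 WT + 2 KO
samples per assay).  Each assay includes a "fill" pseudo-gene padding every
column to 1e6 reads, so CPM and (with the 1-kb lengths in toy_lengths.tsv)
RPKM equal the raw counts and the expression-filter arithmetic can be
checked by hand.

toy_peaks.tsv: per-replicate peak calls with peak height and
replicate/antiserum support (semicolon-separated), for checking the
robust-site thresholds by hand.
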