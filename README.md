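# clipshift

Integrative analysis of RNA-binding-protein (RBP) CLIP binding maps against
RNA abundance and translation, for knockout-versus-wild-type (KO/WT)
designs.

Transcriptome-wide binding maps from HITS-CLIP answer *where* an RBP binds;
they do not by themselves say *what binding does*. clipshift implements the
analysis chain that connects the two, as used for AU-rich-element binding
proteins of the ZFP36 family in activated T cells: robust binding sites are
called from replicated CLIP tag pileups, target mRNAs are classed by
binding region (3'UTR, CDS, intron) and binding magnitude (top-20% peak
height), and each class is tested for shifts in mRNA abundance, for
enrichment of translation-efficiency changes, for ribosome-coverage
magnitude changes, and for association with activation expression
dynamics. A seeded synthetic-data generator produces every input with
known planted structure, so the full pipeline is testable without any
external download.

## The statistics at the core

* **Peak calling with a permutation FDR.** Per gene, candidate peaks are
  maximal runs of positive tag pileup (split at valleys below 50% of the
  flanking maxima) over the annotated transcript extended 10 kb downstream.
  The null re-places the gene's tags uniformly over that span:
  `FDR(h) = E[null peaks with PH >= h] / #observed peaks with PH >= h`,
  monotonized in peak height PH. Robust sites additionally require
  `PH > 5`, support from >= 3 biological replicates and 2 different
  antisera. Cross-link-induced truncation sites (CITS) are positions with
  binomial excess of read 5' ends within a peak.
* **CDF shift tests.** Per-gene normalized `log2(KO/WT)` (median-of-ratios
  normalization, pseudocounted mean ratio) for each target class versus the
  no-site background, two-sided two-sample Kolmogorov-Smirnov.
* **Translation-efficiency delta.**
  `dTE = log2FC(ribosome profiling) - log2FC(RNAseq)`; target classes are
  tested for concentration at the top of the dTE ranking with a pre-ranked
  running-sum enrichment (ES, NES, permutation p, NES-based FDR), each
  class compared against the site-free background.
* **Coverage decomposition.** Sliding-window (20 nt) depth-normalized
  footprint profiles; per-transcript exact binomial test of the KO read
  share against the depth ratio (magnitude), window-profile correlation
  (shape), and a CDS-anchored metagene of per-transcript read-center
  proportions.
* **Cluster enrichment.** k-means (k = 20) on a z-standardized activation
  time course; two-sided Fisher's exact test of target membership per
  cluster.

See `vignettes/clipshift-methods.Rmd` for the full model descriptions,
parameter defaults, and design rationale.

## Worked example

The one-command demo simulates the default synthetic study (1,000 genes;
150 3'UTR, 80 CDS and 60 intron target genes; 5 CLIP replicates across 2
antisera; 4 RNAseq and ribosome-profiling replicates per genotype at depth
10^6) and runs binding-site definition, expression quantification, and the
shift and translation analyses:

```r
library(clipshift)
cfg <- pipeline_config(seed = 42, stages = c("peaks", "expression",
                                             "shift", "translation"))
p <- run_pipeline(cfg, quiet = TRUE)
print(p)
#> clip_pipeline run
#>   robust sites: 290 (genes with sites: 290)
#>   expression: 1000/1000 genes pass filters
#>   abundance shift (KS vs no-site background):
#>     UTR3      n=150  D=0.315 p=4.11e-11 median shift=+0.187
#>     CDS       n=80   D=0.344 p=8.13e-08 median shift=+0.151
#>     intron    n=60   D=0.106 p=0.565 median shift=+0.008
#>     UTR3_top  n=30   D=0.211 p=0.155 median shift=-0.073
#>     CDS_top   n=16   D=0.407 p=0.0111 median shift=+0.161
#>   delta-TE enrichment (pre-ranked):
#>     UTR3      ES=+0.570 NES=+2.72 p=0.002 FDR=0
#>     CDS       ES=+0.805 NES=+3.36 p=0.002 FDR=0
#>     intron    ES=+0.187 NES=+0.82 p=0.96 FDR=0.858
#>     UTR3_top  ES=+0.687 NES=+2.48 p=0.002 FDR=0
#>   elapsed: 13.4 s
```

Reading the output: all 290 planted binding sites are recovered as robust
sites. mRNAs with 3'UTR or CDS binding shift toward higher abundance in the
KO (positive median shift, small KS p) while intron-bound mRNAs do not; the
top-20%-PH 3'UTR subset shows no abundance shift (its planted abundance
effect is zero) although its translation-efficiency enrichment remains
strong — binding magnitude decouples the two effects. CDS targets are more
strongly enriched for increased translation efficiency (NES 3.36) than
3'UTR targets (2.72), and the effect-free intron class is not enriched.

Individual stages are exported (`call_peaks_all()`,
`define_robust_sites()`, `call_cits()`, `kmer_enrichment()`,
`expression_records()`, `run_shift_analysis()`, `enrichment_analysis()`,
`window_coverage()`, `binomial_genotype_test()`, `metagene()`,
`kmeans_timecourse()`, `fisher_cluster_enrichment()`), as are the
synthetic-data generator (`sim_config()`, `simulate_dataset()`,
`write_fixture()`) and the annotation layer (`load_gene_models()`,
`assign_region()`).

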