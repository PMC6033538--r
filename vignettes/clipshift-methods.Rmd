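---
title: "Methods: from CLIP binding maps to abundance and translation effects"
author: "clipshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from CLIP binding maps to abundance and translation effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipshift)
```

# The analysis

clipshift asks a recurring question in post-transcriptional regulation: given
a transcriptome-wide binding map for an RNA-binding protein (RBP) from
HITS-CLIP, what does binding do to its target mRNAs?  The motivating system
is a ZFP36-family AU-rich-element binding protein in activated T cells,
profiled with replicated CLIP, RNAseq and ribosome profiling in a
knockout-versus-wild-type (KO/WT) design, but every stage is generic.  The
pipeline runs:

1. **Binding-site definition.**  CLIP tags are piled up per gene over an
   extended genic span (annotated transcript plus a 10 kb downstream
   extension, to capture non-annotated 3'UTR variants).  Candidate peaks are
   tested against a within-gene permutation null, merged across replicates,
   and kept as *robust sites* when they satisfy joint thresholds on peak
   height (PH > 5, strict), biological-replicate support (>= 3 of 5), and
   antiserum support (2 different antisera).  Cross-link-induced truncation
   sites (CITS) refine peaks to nucleotide resolution.
2. **Target classification.**  Genes are classed by where their robust sites
   fall (3'UTR, CDS, intron; non-exclusive by default, so a gene may carry
   both 3'UTR and CDS sites), and sites are stratified into a top-20% tier
   by PH as a proxy for binding magnitude.
3. **Abundance shifts.**  Normalized per-gene log2(KO/WT) fold changes from
   RNAseq are compared between each target class and the no-site background
   by a two-sided two-sample Kolmogorov-Smirnov test, the classic
   CDF-shift display.
4. **Translation effects.**  The translation-efficiency delta
   `dTE = log2FC(ribosome profiling) - log2FC(RNAseq)` ranks all quantified
   genes; each target class is tested for concentration at the top of the
   ranking with a pre-ranked running-sum enrichment statistic and a
   random-set permutation null (ES, NES, permutation p, NES-based FDR).
5. **Coverage decomposition.**  Per-transcript ribosome-footprint coverage
   is summarized as sliding-window profiles; a per-transcript binomial test
   asks whether reads split between genotypes in proportion to sequencing
   depth, separating a change in magnitude from a change in shape; a
   metagene profile averages per-transcript read-center proportions over the
   coding region.
6. **Time-course context.**  An activation time course is partitioned by
   k-means (k = 20) and each cluster is tested for target
   enrichment/depletion by Fisher's exact test.

# Statistical models and choices

## Peak calling

The pileup depth of tags on a gene is segmented into maximal runs of
positive depth; runs are split at internal valleys that fall below 50% of
the smaller flanking local maximum, which separates adjacent binding sites
without importing a second tool's scan statistic.  The null re-places the
gene's tags (their lengths kept) uniformly over the extended span; with
`n_perm` permutations,

  FDR(h) = E[null candidate peaks with PH >= h] / #observed candidates with PH >= h,

monotonized to be non-increasing in h.  Two numerical points matter.
First, `n_perm` must be at least `2/alpha`: the tail expectation at the
call boundary is otherwise dominated by Monte-Carlo zeros (a candidate
observed once is called whenever the permutations happen to produce none),
which inflates the realized false-call rate; the default is
`n_perm = 200` at `alpha = 0.01`.  Second, the null is memoized across
genes sharing a tag count, tag-length multiset and span width, which makes
dataset-scale calling cheap on simulated data where genes share a geometry.

Robust-site merging uses >= 1 bp overlap and union intervals, with the site
PH the maximum constituent PH.  The PH > 5 threshold is strict; the pooled
preset (all replicates' tags pooled before calling) reads "more than 5
biological replicates" strictly as >= 6 and keeps the 2-antisera rule.
PH-tier ranking breaks ties deterministically (tag count, then site id), and
the top-20% scope defaults to within-region ranking; both scopes exist
because the ranking universe is not fixed by convention.

## CITS

Within a peak of width w containing m truncation positions, each position
with c truncations is tested against Binomial(m, 1/w) (upper tail), with
Benjamini-Hochberg correction across all tested positions.  The synthetic
generator concentrates a configurable fraction of site-tag 5' ends at the
planted cross-link so this stage has a detectable signal.

## Motif stand-in

De novo motif discovery is out of scope; a k-mer enrichment over 30-nt site
windows stands in.  Each k-mer's observed count is compared with
dinucleotide-preserving shuffles (Altschul-Erickson Eulerian-path shuffle)
of the same windows:

  z = (obs - mean_shuffle) / sqrt(sd_shuffle^2 + mean_shuffle + 1).

The unit pseudo-variance in the denominator is deliberate: with 4^8
possible 8-mers most shuffle counts are zero, and an unregularized z-score
is unbounded for any k-mer seen once but absent from the shuffles.  The
regularized score leaves a planted motif far above the null (z > 5 with 40
windows) while null windows stay below |z| ~ 4.

## Fold changes and filters

Counts are normalized by median-of-ratios size factors (per-gene geometric
mean reference over samples; per-sample median ratio) and fold changes are
pseudocounted mean ratios, `log2((mean_KO + 0.5) / (mean_WT + 0.5))`.  This
deliberately replaces a negative-binomial GLM: the downstream analyses
consume only the fold-change values and ranking, and this estimator is
deterministic and oracle-testable.  The expression filters reproduce the
funnel used upstream of every comparison: mean RPKM > 3 in WT or KO
(RNAseq) AND cpm > 1 in at least two replicates of either genotype
(ribosome profiling); both thresholds strict.

One identifiability point is worth stating plainly: a blind global
normalization anchors the count scale on the bulk of genes.  When a
substantial fraction of genes shifts in one direction (29% of genes in the
default synthetic conditions), the anchor itself moves by a small constant
(about -0.03 log2 here for RNA, about -0.08 for the ribosome-profiling
derived dTE), and *absolute* per-gene fold changes inherit it.  No
estimator can remove this constant without oracle knowledge of the null
genes.  All analyses in the pipeline are therefore contrasts against the
no-site background (KS shifts, enrichment versus background, and the
parameter-recovery checks in the test suite), for which the constant
cancels.

## KS, binomial, Fisher

The two-sample KS test is two-sided, with exact p-values when
`n_x * n_y <= 10^4` and the asymptotic Kolmogorov distribution otherwise.
The per-transcript binomial test and the per-cluster Fisher test are exact
two-sided (minimum-likelihood) tests.  All three are delegated to the
standard stats implementations and are verified against brute-force
enumeration oracles in the test suite; Benjamini-Hochberg q-values are
reported across transcripts and across clusters, and across the family of
class KS tests alongside (never replacing) raw p-values.

## Pre-ranked enrichment

Walking down the dTE-ranked list, the running sum gains
`|score|^p / sum_hits |score|^p` at set members and loses `1/(N - N_hits)`
elsewhere; ES is the signed maximum deviation, p = 1 by default (p = 0
gives the unweighted statistic with the exact set/complement antisymmetry
the tests exploit).  The null draws random gene sets of matching size; NES
divides ES by the mean |null ES| of matching sign; the permutation p is
add-one corrected; the family FDR is the standard NES-based ratio over the
pooled sign-normalized null.  Each class is evaluated on the ranking
restricted to its own members plus the site-free background — the
comparison the analysis is defined as — because with several planted
classes in one ranking, one class's true signal would otherwise masquerade
as another's depletion.

## Coverage

"Coverage" counts read centers throughout, matching the metagene
definition of per-position proportions.  The binomial unit is the whole
transcript with null KO fraction `depth_KO / (depth_KO + depth_WT)`;
windows (20 nt, step 1, reads per window per million) are display
machinery.  The metagene includes transcripts with >= 10 reads in the
region of interest (CDS by default), converts each to a proportion vector
(summing to 1, zeros included over the transcript's full extent), and
averages position-wise over the transcripts represented at each position.
The default anchoring is two-sided: nucleotide-resolved flanks at the CDS
start and stop with the CDS middle scaled into a fixed number of bins.

A sampling caveat documented for the shape/magnitude decomposition: the
WT-KO correlation of window profiles measures the shared shape only once
per-window expected counts dominate shot noise.  At ~2,000 reads per
transcript the correlation plateaus near 0.9 from Poisson noise alone even
with an identical underlying shape; at ~20,000 reads it exceeds 0.95.  The
coverage checks therefore run at profiling-grade per-transcript depth
(dedicated bundle: 200 transcripts, 4 x 10^6 pooled reads per genotype).

## Clustering

Genes are z-standardized across timepoints and partitioned with multi-start
k-means (best of `n_init` random starts, fully seeded), the behavioral
equivalent of the classic pattern-partitioning workflow; Euclidean distance
on z-scores is the default metric.  Cluster summaries report the three most
enriched and most depleted clusters (p ascending, ties by |log OR| then
cluster id).

# The synthetic-data generator

`simulate_dataset()` produces the whole input bundle from one seeded
configuration; each artifact (plan, tags, RNA counts, ribosome counts,
coverage, time course, sequences) draws from its own stream derived from
the global seed, so adding an output never perturbs the others.

The default configuration *is* the study condition exercised by the
acceptance suite: 1,000 genes sharing a two-exon geometry (200 nt 5'UTR,
900 nt CDS, 500 nt intron, 800 nt 3'UTR, alternating strands, 10 kb
downstream extensions); 150 UTR3 / 80 CDS / 60 intron target genes drawn
from the upper 70% of baseline abundance; site tags Poisson(lambda = 10
bulk, 25 top tier) per replicate with lognormal per-replicate jitter (sd
0.15) over a uniform background of 0.3 tags/kb; 5 replicates across 2
antisera (3 + 2); NB counts (variance mu + 0.05 mu^2) at depth 10^6 with 4
replicates per genotype; planted log2 genotype effects delta_abund(UTR3) =
0.2 (but 0 in the top PH tier — the blunted-top-quintile structure),
delta_abund(CDS) = 0.2, delta_TE(UTR3) = 0.3 < delta_TE(CDS) = 0.5, and an
all-zero intron class; coverage shapes shared between genotypes and scaled
by 2^delta_TE; a 6-archetype, 8-timepoint activation time course in which
UTR3/CDS targets follow the rapidly-induced archetype with probability
0.6.  The planted site sequence embeds the AU-rich 8-mer UAUUUAUU in a
30-nt window.  Effect sizes are free parameters of the generator — the
source analyses report CDF curves and p-values, not effect magnitudes — and
are documented as such.

What the generator does *not* emulate: real isoform structure and
alternative polyadenylation, mappability and GC biases, PCR duplicates and
UMI structure, overdispersion heterogeneity across genes, or compositional
library effects beyond the one-directional target shift.  Passing tests
demonstrate that the statistical machinery recovers planted structure under
these idealized conditions; they do not certify performance on real
libraries.

# Problem sizes in the checks

The packaged checks run, per seed, the full 1,000-gene bundle through peaks
-> expression -> shift -> enrichment (about 10-15 s); structural criteria
aggregate 20 seeds, calibration uses 200 null genes, recovery averages 10
seeds, and the coverage decomposition uses the 200-transcript dedicated
bundle.  These sizes were chosen so each Monte-Carlo band (for example the
0.05 log2 recovery band, ~5 standard errors at class size 60 x 10 seeds)
is comfortably wider than the corresponding sampling noise.

# Known limitations

* The permutation FDR is calibrated for the uniform-background null it
  states; structured backgrounds (mappability, expression-coupled tag
  density) would need a matched null.
* The pooled-mode support rule (">5 replicates" as >= 6) and the top-20%
  ranking scope are genuinely underdetermined conventions; both are
  configurable and the defaults are stated.
* NES/FDR values from the enrichment stage are reproducible only in
  distribution across reimplementations; seeds make them exactly
  reproducible within this one.
* Exact binomial and Fisher tests are conservative at small counts; the
  q-values inherit that conservatism.
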