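## Small in-code fixtures shared across test files.

## two-exon plus-strand coding gene:
## exons [100,200) + [300,500); CDS span [150,400); 1 kb downstream ext
fix_gene_plus <- function(downstream = 1000L) {
  gene_model("gP", "chr1", "+", rbind(c(100L, 200L), c(300L, 500L)),
             c(150L, 400L), downstream)
}

## its exact mirror on the minus strand: coordinates reflected about 2600
## (x -> 2600 - x), placed high enough that the upstream-pointing downstream
## extension is never clipped at coordinate 0
fix_gene_minus <- function(downstream = 1000L) {
  gene_model("gM", "chr1", "-", rbind(c(2100L, 2300L), c(2400L, 2500L)),
             c(2200L, 2450L), downstream)
}

## tag table builder
fix_tags <- function(starts, len = 35L, chrom = "chr1", strand = "+",
                     replicate = "r1", antiserum = "A") {
  clip_tags(data.frame(chrom = chrom, start = as.integer(starts),
                       end = as.integer(starts + len), strand = strand,
                       replicate = replicate, antiserum = antiserum))
}

## peak-table row with provenance list-columns (for robust-site tests)
fix_peak <- function(gene = "g1", start = 0L, end = 50L, ph = 6L,
                     reps = c("r1", "r2", "r3"), sera = c("A", "A", "B"),
                     n_tags = NULL, strand = "+") {
  df <- data.frame(chrom = "chr1", start = start, end = end, strand = strand,
                   gene_id = gene, ph = ph, n_tags = n_tags %||% ph,
                   fdr = 0.001)
  df$replicates <- list(unique(reps))
  df$antisera <- list(unique(sera))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## tiny count_matrix pair with hand-set counts (2 WT + 2 KO per assay)
fix_count_pair <- function(rna_counts, rp_counts, lengths = NULL) {
  genes <- rownames(rna_counts)
  lengths <- lengths %||% stats::setNames(rep(1000, length(genes)), genes)
  meta <- function(assay) data.frame(
    sample = colnames(rna_counts), genotype = rep(c("WT", "KO"), each = 2L),
    replicate = c(1L, 2L, 1L, 2L), assay = assay)
  list(rna = count_matrix(rna_counts, meta("rnaseq"), lengths),
       rp = count_matrix(rp_counts, meta("riboprof"), lengths))
}
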