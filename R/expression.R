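#' Count matrix with sample metadata and gene lengths
#'
#' Container for a genes-by-samples integer count matrix from RNAseq or
#' ribosome profiling, together with the sample metadata (genotype,
#' replicate, assay) and per-gene effective lengths used for RPKM.
#'
#' @param counts integer matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).
#' @param meta data.frame with one row per sample: `sample`, `genotype`
#'   (`"WT"`/`"KO"`), `replicate`, `assay` (`"rnaseq"`/`"riboprof"`).
#' @param lengths named numeric vector of effective gene lengths (nt).
#' @return a list of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, meta, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_("counts needs gene rownames and sample colnames")
  if (any(counts < 0)) stop_("negative counts")
  need <- c("sample", "genotype", "replicate", "assay")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_("meta missing column(s): %s", paste(miss, collapse = ", "))
  if (!setequal(meta$sample, colnames(counts)))
    stop_("meta samples do not match count columns")
  if (!all(meta$genotype %in% c("WT", "KO"))) stop_("genotype must be WT or KO")
  if (!all(meta$assay %in% c("rnaseq", "riboprof"))) stop_("assay must be rnaseq or riboprof")
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) stop_("every gene needs a positive length")
  structure(list(counts = counts, meta = meta, lengths = lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s; %d WT, %d KO)\n",
              nrow(x$counts), ncol(x$counts), x$meta$assay[1L],
              sum(x$meta$genotype == "WT"), sum(x$meta$genotype == "KO")))
  invisible(x)
}

#' Counts per million
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of CPM values (each column sums to 10^6).
#' @export
compute_cpm <- function(cm) {
  libs <- colSums(cm$counts)
  if (any(libs == 0)) stop_("sample with zero library size")
  sweep(cm$counts, 2L, libs, "/") * 1e6
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / ((length/10^3) * (library_size/10^6))`.
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of RPKM values.
#' @export
compute_rpkm <- function(cm) {
  libs <- colSums(cm$counts)
  if (any(libs == 0)) stop_("sample with zero library size")
  sweep(sweep(cm$counts, 2L, libs / 1e6, "/"), 1L, cm$lengths / 1e3, "/")
}

## per-genotype mean of a per-sample matrix
.genotype_means <- function(mat, genotype) {
  cbind(WT = rowMeans(mat[, genotype == "WT", drop = FALSE]),
        KO = rowMeans(mat[, genotype == "KO", drop = FALSE]))
}

#' Expression filters for downstream shift and translation analyses
#'
#' A gene enters the CDF-shift and delta-TE analyses iff its mean RPKM
#' exceeds `rpkm_min` in WT or KO replicates of the RNAseq assay AND its CPM
#' exceeds `cpm_min` in at least `cpm_min_samples` replicates of either
#' genotype in the ribosome-profiling assay.
#'
#' @param rna RNAseq [count_matrix()].
#' @param rp ribosome-profiling [count_matrix()].
#' @param rpkm_min mean-RPKM threshold, strict (default 3).
#' @param cpm_min CPM threshold, strict (default 1).
#' @param cpm_min_samples replicate support for the CPM rule (default 2).
#' @return data.frame: `gene_id`, `passes_rna`, `passes_rp`, `pass`,
#'   `reason` (`""`, `"rna_filter"`, `"rp_filter"`, `"rna_filter+rp_filter"`,
#'   or `"missing_assay"` for genes absent from one assay).
#' @export
filter_genes <- function(rna, rp, rpkm_min = 3, cpm_min = 1, cpm_min_samples = 2L) {
  genes <- union(rownames(rna$counts), rownames(rp$counts))
  in_rna <- genes %in% rownames(rna$counts)
  in_rp <- genes %in% rownames(rp$counts)

  rpkm_gm <- .genotype_means(compute_rpkm(rna), rna$meta$genotype)
  p_rna <- apply(rpkm_gm > rpkm_min, 1L, any)[genes]
  p_rna[!in_rna] <- FALSE

  cpm <- compute_cpm(rp)
  ok <- cpm > cpm_min
  n_wt <- rowSums(ok[, rp$meta$genotype == "WT", drop = FALSE])
  n_ko <- rowSums(ok[, rp$meta$genotype == "KO", drop = FALSE])
  p_rp <- (pmax(n_wt, n_ko) >= cpm_min_samples)[genes]
  p_rp[!in_rp] <- FALSE

  reason <- rep("", length(genes))
  reason[!p_rna] <- "rna_filter"
  reason[!p_rp] <- ifelse(nzchar(reason[!p_rp]), "rna_filter+rp_filter", "rp_filter")
  reason[!in_rna | !in_rp] <- "missing_assay"
  data.frame(gene_id = genes, passes_rna = unname(p_rna), passes_rp = unname(p_rp),
             pass = unname(p_rna & p_rp & in_rna & in_rp), reason = reason)
}

#' Median-of-ratios size factors
#'
#' Reference = per-gene geometric mean across samples (genes expressed in
#' every sample); size factor = per-sample median count/reference ratio.
#'
#' @param counts genes-by-samples count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  logs <- log(counts)
  use <- is.finite(rowSums(logs))
  if (!any(use)) stop_("no gene expressed in every sample; cannot normalize")
  ref <- rowMeans(logs[use, , drop = FALSE])
  apply(logs[use, , drop = FALSE], 2L, function(lc) exp(stats::median(lc - ref)))
}

#' Normalized per-gene log2 fold change (KO/WT)
#'
#' Counts are scaled by per-sample normalization factors (median-of-ratios,
#' or plain library size), averaged within genotype, and the fold change is
#' `log2((mean_KO + pc) / (mean_WT + pc))` with pseudocount `pc`.
#' Deterministic for fixed inputs; an all-zero gene returns 0.
#'
#' @param cm a [count_matrix()].
#' @param pseudocount pseudocount added to both normalized means (default 0.5;
#'   must be > 0).
#' @param normalization `"median_of_ratios"` (default) or `"library_size"`.
#' @return data.frame: `gene_id`, `mean_wt`, `mean_ko` (normalized), `log2fc`.
#' @export
estimate_log2fc <- function(cm, pseudocount = 0.5,
                            normalization = c("median_of_ratios", "library_size")) {
  normalization <- match.arg(normalization)
  if (pseudocount <= 0) stop_("pseudocount must be > 0")
  if (!all(c("WT", "KO") %in% cm$meta$genotype))
    stop_("need at least one replicate per genotype")
  sf <- if (normalization == "median_of_ratios") size_factors(cm$counts)
        else { libs <- colSums(cm$counts); libs / mean(libs) }
  norm <- sweep(cm$counts, 2L, sf, "/")
  gm <- .genotype_means(norm, cm$meta$genotype)
  data.frame(gene_id = rownames(cm$counts), mean_wt = unname(gm[, "WT"]),
             mean_ko = unname(gm[, "KO"]),
             log2fc = unname(log2((gm[, "KO"] + pseudocount) /
                                  (gm[, "WT"] + pseudocount))))
}

#' Joint expression table for shift and translation analyses
#'
#' Combines filters and normalized fold changes from both assays into one
#' per-gene record, including the translation-efficiency delta
#' `dte = log2fc_rp - log2fc_rna` for genes passing both filters.
#'
#' @inheritParams filter_genes
#' @inheritParams estimate_log2fc
#' @return data.frame: `gene_id`, `passes_rna`, `passes_rp`, `pass`,
#'   `log2fc_rna`, `log2fc_rp`, `dte`.
#' @export
expression_records <- function(rna, rp, rpkm_min = 3, cpm_min = 1,
                               cpm_min_samples = 2L, pseudocount = 0.5,
                               normalization = "median_of_ratios") {
  flt <- filter_genes(rna, rp, rpkm_min, cpm_min, cpm_min_samples)
  fc_rna <- estimate_log2fc(rna, pseudocount, normalization)
  fc_rp <- estimate_log2fc(rp, pseudocount, normalization)
  flt$log2fc_rna <- fc_rna$log2fc[match(flt$gene_id, fc_rna$gene_id)]
  flt$log2fc_rp <- fc_rp$log2fc[match(flt$gene_id, fc_rp$gene_id)]
  flt$dte <- flt$log2fc_rp - flt$log2fc_rna
  flt
}
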