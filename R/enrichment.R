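#' Translation-efficiency delta per gene
#'
#' `dte = log2fc_rp - log2fc_rna`: the between-genotype (KO/WT) difference
#' in ribosome association beyond what the change in mRNA abundance
#' explains.  Genes missing either fold change (or failing the expression
#' filters) are excluded.
#'
#' @param records output of [expression_records()].
#' @return data.frame: `gene_id`, `log2fc_rna`, `log2fc_rp`, `dte`.
#' @export
compute_dte <- function(records) {
  keep <- records$pass & is.finite(records$log2fc_rna) & is.finite(records$log2fc_rp)
  out <- records[keep, c("gene_id", "log2fc_rna", "log2fc_rp"), drop = FALSE]
  out$dte <- out$log2fc_rp - out$log2fc_rna
  rownames(out) <- NULL
  out
}

#' Rank genes by the delta-TE metric
#'
#' Total order, `dte` descending; ties broken by lexicographic `gene_id` so
#' the ranking is deterministic.
#'
#' @param records output of [compute_dte()] (needs `gene_id` and `dte`).
#' @return named numeric vector of `dte` scores, names = gene ids, sorted.
#' @export
rank_genes <- function(records) {
  if (nrow(records) < 2L) stop_("need at least 2 genes to rank")
  if (anyDuplicated(records$gene_id)) stop_("duplicate gene_id in ranking input")
  o <- order(-records$dte, records$gene_id)
  stats::setNames(records$dte[o], records$gene_id[o])
}

## running-sum enrichment statistic; scores sorted descending, hit logical.
## Returns list(es, running, extremum_index).
.es_stat <- function(scores, hit, weight_p = 1) {
  n <- length(scores)
  n_hit <- sum(hit)
  w <- abs(scores)^weight_p
  inc <- numeric(n)
  denom <- sum(w[hit])
  inc[hit] <- if (denom > 0) w[hit] / denom else 1 / n_hit  # all-zero scores
  inc[!hit] <- -1 / (n - n_hit)
  running <- cumsum(inc)
  i_star <- which.max(abs(running))
  list(es = running[i_star], running = running, extremum = i_star)
}

#' Pre-ranked running-sum enrichment of a gene set
#'
#' Classic pre-ranked GSEA statistic: walking down the ranked list, the
#' running sum gains `|score|^p / sum_hits |score|^p` at gene-set members and
#' loses `1/(N - N_hits)` at non-members; the enrichment score (ES) is the
#' signed maximum deviation.  The null is built from `n_perm` uniformly
#' random gene sets of the same size.  `NES = ES / mean(|null ES| of the
#' matching sign)`; the permutation p-value is the add-one-corrected
#' fraction of null `|ES| >= |ES_obs|`.  The leading edge is the set members
#' at or before the ES extremum (after it for negative ES).
#'
#' @param ranked named numeric vector from [rank_genes()] (scores sorted
#'   descending).
#' @param gene_set character vector; must intersect the ranking and not
#'   cover it entirely.
#' @param weight_p score-weighting exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov-like statistic).
#' @param n_perm number of random-set permutations.
#' @param seed integer seed (mandatory for reproducibility).
#' @return list of class `"enrichment_result"`: `set_name`, `es`, `nes`,
#'   `p_value`, `leading_edge`, `n_hits`, `n_perm`, `seed`, `null_es`.
#' @export
preranked_enrichment <- function(ranked, gene_set, weight_p = 1,
                                 n_perm = 1000L, seed = 1L) {
  genes <- names(ranked)
  hit <- genes %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop_("gene set does not intersect the ranked list")
  if (n_hit == length(genes)) stop_("gene set covers the whole ranked list")
  obs <- .es_stat(ranked, hit, weight_p)

  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(b) {
    h <- logical(length(genes))
    h[sample.int(length(genes), n_hit)] <- TRUE
    .es_stat(ranked, h, weight_p)$es
  }, numeric(1L))

  same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  le_idx <- if (obs$es >= 0) which(hit[seq_len(obs$extremum)])
            else obs$extremum - 1L + which(hit[obs$extremum:length(genes)])
  structure(list(set_name = NULL, es = obs$es, nes = nes, p_value = p,
                 leading_edge = genes[le_idx], n_hits = n_hit,
                 n_perm = n_perm, seed = seed, null_es = null_es,
                 running = obs$running),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result%s: ES %.3f, NES %.3f, p %.4g (%d hits, %d perms)\n",
              if (!is.null(x$set_name)) paste0(" [", x$set_name, "]") else "",
              x$es, x$nes, x$p_value, x$n_hits, x$n_perm))
  invisible(x)
}

#' Enrichment of several gene sets with an NES-based family FDR
#'
#' Runs [preranked_enrichment()] for each set and computes the standard
#' NES-based FDR over the family: for a set with `NES* >= 0`,
#' `q = [#(null NES >= NES*) / #(null NES >= 0)] /
#'      [#(observed NES >= NES*) / #(observed NES >= 0)]`, capped at 1
#' (mirrored for negative NES); null NES pool all sets' sign-normalized
#' permutation scores.
#'
#' @param ranked named score vector from [rank_genes()].
#' @param gene_sets named list of character vectors.
#' @param background optional character vector of comparison genes (e.g. the
#'   site-free background).  When supplied, each set is evaluated on the
#'   ranking restricted to its own members plus the background, so one
#'   class's planted signal cannot masquerade as another class's depletion;
#'   this matches an analysis defined as "targets versus mRNAs with no
#'   binding sites".  Default `NULL` uses the full ranking for every set.
#' @inheritParams preranked_enrichment
#' @return data.frame: `set`, `n_hits`, `es`, `nes`, `p_value`, `fdr`,
#'   `leading_edge` (semicolon-joined); individual results in attribute
#'   `"results"`.
#' @export
enrichment_analysis <- function(ranked, gene_sets, weight_p = 1,
                                n_perm = 1000L, seed = 1L, background = NULL) {
  if (is.null(names(gene_sets))) stop_("gene_sets must be named")
  res <- lapply(seq_along(gene_sets), function(i) {
    rk <- ranked
    if (!is.null(background))
      rk <- ranked[names(ranked) %in% c(gene_sets[[i]], background)]
    r <- preranked_enrichment(rk, gene_sets[[i]], weight_p, n_perm,
                              seed = derive_seed(seed, i))
    r$set_name <- names(gene_sets)[i]
    r
  })
  ## sign-matched normalization of each set's null ES -> pooled null NES
  null_nes <- unlist(lapply(res, function(r) {
    pos <- r$null_es[r$null_es >= 0]; neg <- r$null_es[r$null_es < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) neg / mean(abs(neg)))
  }))
  obs_nes <- vapply(res, `[[`, numeric(1L), "nes")
  fdr <- vapply(obs_nes, function(s) {
    if (is.na(s)) return(NA_real_)
    if (s >= 0) {
      num <- sum(null_nes >= s) / max(1L, sum(null_nes >= 0))
      den <- sum(obs_nes >= s, na.rm = TRUE) / max(1L, sum(obs_nes >= 0, na.rm = TRUE))
    } else {
      num <- sum(null_nes <= s) / max(1L, sum(null_nes < 0))
      den <- sum(obs_nes <= s, na.rm = TRUE) / max(1L, sum(obs_nes < 0, na.rm = TRUE))
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1L))
  out <- data.frame(set = names(gene_sets),
                    n_hits = vapply(res, `[[`, integer(1L), "n_hits"),
                    es = vapply(res, `[[`, numeric(1L), "es"),
                    nes = obs_nes,
                    p_value = vapply(res, `[[`, numeric(1L), "p_value"),
                    fdr = fdr,
                    leading_edge = vapply(res, function(r)
                      paste(r$leading_edge, collapse = ";"), character(1L)))
  attr(out, "results") <- stats::setNames(res, names(gene_sets))
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop_("%s: line %d has fewer than 3 fields", path, bad[1L])
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1L), 1L))
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}
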