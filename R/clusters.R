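#' k-means partitioning of a time-course expression matrix
#'
#' Genes are z-standardized across timepoints, then partitioned with
#' multi-start k-means (best of `n_init` random initializations by total
#' within-cluster sum of squares), deterministic under a fixed seed.
#' Genes with zero variance across timepoints cannot be standardized and
#' raise an error.
#'
#' @param tm numeric matrix, genes x timepoints (rownames = gene ids).
#' @param k number of clusters (default 20, the granularity at which
#'   activation-pattern classes separate in T-cell time courses).
#' @param n_init number of random initializations (default 10).
#' @param seed integer seed.
#' @param iter_max maximum Lloyd iterations per start.
#' @return list of class `"timecourse_clustering"`: `cluster` (named integer
#'   vector), `centers` (k x timepoints, standardized scale), `z` (the
#'   standardized matrix), `k`, `seed`.
#' @export
kmeans_timecourse <- function(tm, k = 20L, n_init = 10L, seed = 1L,
                              iter_max = 50L) {
  tm <- as.matrix(tm)
  if (k > nrow(tm)) stop_("k = %d exceeds the number of genes (%d)", k, nrow(tm))
  if (is.null(rownames(tm))) stop_("time-course matrix needs gene rownames")
  sds <- apply(tm, 1L, stats::sd)
  if (any(sds == 0)) stop_("gene(s) with zero variance across timepoints")
  z <- (tm - rowMeans(tm)) / sds
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = iter_max)
  structure(list(cluster = stats::setNames(km$cluster, rownames(tm)),
                 centers = km$centers, z = z, k = k, seed = seed),
            class = "timecourse_clustering")
}

#' @export
print.timecourse_clustering <- function(x, ...) {
  cat(sprintf("timecourse_clustering: %d genes in %d clusters (seed %d)\n",
              length(x$cluster), x$k, x$seed))
  invisible(x)
}

#' Fisher's exact enrichment of a target set across clusters
#'
#' For each cluster, builds the 2x2 table (in-cluster vs not, target vs not)
#' over the clustered gene universe and applies the two-sided Fisher exact
#' test (minimum-likelihood summation of hypergeometric probabilities, via
#' [stats::fisher.test()]); Benjamini-Hochberg q-values are computed across
#' the k clusters.  The odds ratio is the unconditional sample estimate
#' `(a d) / (b c)`, with infinite values flagged.
#'
#' @param clustering a [kmeans_timecourse()] result (or any named
#'   cluster-assignment vector).
#' @param target_set character vector of target gene ids; must be a
#'   non-empty subset of the clustered genes.
#' @return data.frame: `cluster`, `n_in_cluster`, `n_targets_in_cluster`,
#'   `odds_ratio`, `or_infinite`, `p_value`, `q_value`, `direction`.
#' @export
fisher_cluster_enrichment <- function(clustering, target_set) {
  assign <- if (inherits(clustering, "timecourse_clustering")) clustering$cluster
            else clustering
  target_set <- intersect(target_set, names(assign))
  if (length(target_set) == 0L) stop_("empty target set (after intersection with universe)")
  is_t <- names(assign) %in% target_set
  res <- lapply(sort(unique(assign)), function(cl) {
    inc <- assign == cl
    a <- sum(inc & is_t); b <- sum(inc & !is_t)
    c_ <- sum(!inc & is_t); d <- sum(!inc & !is_t)
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))
    or <- (a * d) / (b * c_)
    data.frame(cluster = cl, n_in_cluster = sum(inc), n_targets_in_cluster = a,
               odds_ratio = or, or_infinite = is.infinite(or),
               p_value = ft$p.value,
               direction = if (a / max(1L, sum(inc)) >= length(target_set) / length(assign))
                 "enriched" else "depleted")
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out[, c("cluster", "n_in_cluster", "n_targets_in_cluster", "odds_ratio",
          "or_infinite", "p_value", "q_value", "direction")]
}

#' Mean profiles of the most target-enriched and -depleted clusters
#'
#' Selects the `n_top` clusters per direction by ascending p-value (ties by
#' descending `|log odds ratio|`, then cluster id) and returns the
#' position-wise mean standardized expression of their member genes.
#'
#' @param clustering a [kmeans_timecourse()] result.
#' @param enrichment output of [fisher_cluster_enrichment()].
#' @param n_top clusters per direction (default 3; fewer available clusters
#'   are used with a warning).
#' @return data.frame: `direction`, `cluster`, `p_value`, one column per
#'   timepoint with the mean standardized profile.
#' @export
summarize_clusters <- function(clustering, enrichment, n_top = 3L) {
  pick <- function(dir) {
    e <- enrichment[enrichment$direction == dir, , drop = FALSE]
    if (nrow(e) < n_top)
      warning(sprintf("only %d %s cluster(s) available", nrow(e), dir))
    lor <- abs(log(pmax(e$odds_ratio, .Machine$double.eps)))
    lor[e$or_infinite] <- Inf
    e[order(e$p_value, -lor, e$cluster), , drop = FALSE][seq_len(min(n_top, nrow(e))), ]
  }
  sel <- rbind(cbind(direction = "enriched", pick("enriched")),
               cbind(direction = "depleted", pick("depleted")))
  prof <- t(vapply(sel$cluster, function(cl)
    colMeans(clustering$z[clustering$cluster == cl, , drop = FALSE]),
    numeric(ncol(clustering$z))))
  cbind(sel[, c("direction", "cluster", "p_value")], as.data.frame(prof))
}
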