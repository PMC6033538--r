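#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: peak-calling FDR and
#' permutation count, robust-site thresholds (strict PH > 5, >= 3
#' replicates, 2 antisera), PH stratification (top 20%, per-region scope),
#' expression filters (mean RPKM > 3 in either genotype; CPM > 1 in >= 2
#' replicates of either genotype), the fold-change pseudocount and
#' normalization, annotation mode, enrichment permutations, coverage window
#' and metagene read filter, time-course k, the global seed, and stage
#' toggles.
#'
#' @param seed global seed; per-stage seeds derive from it.
#' @param sim a [sim_config()] used when no bundle is supplied; defaults to
#'   `sim_config(seed = derive_seed(seed, 11))`.
#' @param fdr peak FDR threshold.
#' @param n_perm peak-calling permutations.
#' @param min_ph,min_replicates,min_antisera robust-site thresholds.
#' @param top_fraction,tier_scope PH stratification.
#' @param annotation_mode `"non_exclusive"` or `"exclusive"`.
#' @param cits_stringent restrict classification to sites overlapping a
#'   robust CITS.
#' @param rpkm_min,cpm_min,cpm_min_samples expression filters.
#' @param pseudocount,normalization fold-change estimator settings.
#' @param gsea_nperm,gsea_weight pre-ranked enrichment settings.
#' @param window coverage window length (nt).
#' @param min_reads metagene read filter.
#' @param k,n_init time-course clustering settings.
#' @param stages character vector of stages to run (dependency order is
#'   enforced internally): any of `"peaks"`, `"expression"`, `"shift"`,
#'   `"translation"`, `"coverage"`, `"clusters"`.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, fdr = 0.01, n_perm = 200L,
                            min_ph = 5L, min_replicates = 3L, min_antisera = 2L,
                            top_fraction = 0.2,
                            tier_scope = c("per_region", "global"),
                            annotation_mode = c("non_exclusive", "exclusive"),
                            cits_stringent = FALSE,
                            rpkm_min = 3, cpm_min = 1, cpm_min_samples = 2L,
                            pseudocount = 0.5,
                            normalization = "median_of_ratios",
                            gsea_nperm = 500L, gsea_weight = 1,
                            window = 20L, min_reads = 10L,
                            k = 20L, n_init = 5L,
                            stages = c("peaks", "expression", "shift",
                                       "translation", "coverage", "clusters")) {
  tier_scope <- match.arg(tier_scope)
  annotation_mode <- match.arg(annotation_mode)
  stages <- match.arg(stages, several.ok = TRUE)
  if (fdr <= 0 || fdr > 1) stop_("fdr must be in (0, 1]")
  if (top_fraction <= 0 || top_fraction > 1) stop_("top_fraction must be in (0, 1]")
  structure(as.list(environment()), class = "pipeline_config")
}

.stage_cache <- function(out_dir, name, recompute, fun) {
  if (!is.null(out_dir)) {
    f <- file.path(out_dir, sprintf("stage_%s.rds", name))
    if (!recompute && file.exists(f))
      return(list(value = readRDS(f), recomputed = FALSE))
    value <- fun()
    saveRDS(value, f, version = 2)
    return(list(value = value, recomputed = TRUE))
  }
  list(value = fun(), recomputed = TRUE)
}

#' Run the integrative pipeline end to end
#'
#' Executes, in dependency order: peak calling and robust-site definition
#' with region annotation and PH tiers; expression quantification, filters
#' and fold changes; abundance CDF-shift tests per target class;
#' delta-TE ranking with pre-ranked enrichment of the target sets;
#' footprint coverage tests and metagene profiles; and time-course cluster
#' enrichment.  With `out_dir` set, each stage's result is cached on disk
#' and reused on rerun (delete a stage file to recompute it and everything
#' only it feeds); the manifest records an md5 checksum per stage.
#'
#' @param cfg a [pipeline_config()].
#' @param bundle input data: a [simulate_dataset()] bundle (default: one is
#'   simulated from `cfg$sim`).
#' @param out_dir optional directory for stage caches and the manifest.
#' @param quiet suppress per-stage log lines.
#' @return a list of class `"clip_pipeline"` with elements `sites`,
#'   `assignments`, `records`, `shift`, `translation`, `coverage`,
#'   `clusters`, `manifest`, `cfg`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), bundle = NULL,
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(bundle)) {
    sim_cfg <- cfg$sim %||% sim_config(seed = derive_seed(cfg$seed, 11L))
    bundle <- simulate_dataset(sim_cfg)
    say("simulated bundle: %d genes, %d tags", nrow(bundle$truth), nrow(bundle$tags))
  }
  res <- list(cfg = cfg)
  manifest <- list(seed = cfg$seed, stages = list())
  note <- function(name, value, recomputed, n_rows) {
    manifest$stages[[name]] <<- list(checksum = .checksum(value),
                                     recomputed = recomputed, n = n_rows)
  }
  want <- function(s) s %in% cfg$stages

  if (want("peaks")) {
    st <- .stage_cache(out_dir, "peaks", FALSE, function() {
      set.seed(derive_seed(cfg$seed, 21L))
      peaks <- call_peaks_all(bundle$tags, bundle$models, "per_replicate",
                              alpha = cfg$fdr, n_perm = cfg$n_perm)
      sites <- define_robust_sites(peaks, cfg$min_ph, cfg$min_replicates,
                                   cfg$min_antisera)
      sites <- annotate_sites(sites, bundle$models)
      if (nrow(sites) > 0L)
        sites <- stratify_by_ph(sites, cfg$top_fraction, cfg$tier_scope)
      cits <- call_cits(bundle$tags, sites)
      if (cfg$cits_stringent) sites <- restrict_to_cits(sites, cits)
      list(peaks = peaks, sites = sites, cits = cits)
    })
    res$peaks <- st$value$peaks
    res$sites <- st$value$sites
    res$cits <- st$value$cits
    note("peaks", st$value, st$recomputed, nrow(res$sites))
    say("peaks: %d per-replicate peaks -> %d robust sites (%d CITS)",
        nrow(res$peaks), nrow(res$sites), nrow(res$cits))
  }

  if (want("expression")) {
    st <- .stage_cache(out_dir, "expression", FALSE, function()
      expression_records(bundle$rna, bundle$rp, cfg$rpkm_min, cfg$cpm_min,
                         cfg$cpm_min_samples, cfg$pseudocount,
                         cfg$normalization))
    res$records <- st$value
    note("expression", st$value, st$recomputed, sum(res$records$pass))
    say("expression: %d/%d genes pass the joint filter",
        sum(res$records$pass), nrow(res$records))
  }

  if (want("shift") || want("translation")) {
    if (is.null(res$sites) || is.null(res$records))
      stop_("stage 'shift'/'translation' needs upstream stages 'peaks' and 'expression'")
    res$assignments <- classify_targets(res$sites, bundle$models,
                                        cfg$annotation_mode)
  }

  if (want("shift")) {
    st <- .stage_cache(out_dir, "shift", FALSE, function()
      run_shift_analysis(res$assignments, res$records, "log2fc_rna"))
    res$shift <- st$value
    note("shift", st$value, st$recomputed, nrow(res$shift))
    say("shift: %s", paste(sprintf("%s p=%.2g", res$shift$class,
                                   res$shift$p_value), collapse = ", "))
  }

  if (want("translation")) {
    st <- .stage_cache(out_dir, "translation", FALSE, function() {
      dte <- compute_dte(res$records)
      ranked <- rank_genes(dte)
      asg <- res$assignments
      sets <- list(UTR3 = asg$gene_id[asg$UTR3], CDS = asg$gene_id[asg$CDS],
                   intron = asg$gene_id[asg$intron],
                   UTR3_top = asg$gene_id[asg$UTR3_top])
      sets <- lapply(sets, intersect, names(ranked))
      sets <- sets[lengths(sets) > 0L]
      ## each class is compared against the site-free background
      bg <- intersect(asg$gene_id[!asg$is_target], names(ranked))
      list(ranked = ranked,
           enrichment = enrichment_analysis(ranked, sets, cfg$gsea_weight,
                                            cfg$gsea_nperm,
                                            seed = derive_seed(cfg$seed, 22L),
                                            background = bg))
    })
    res$translation <- st$value$enrichment
    res$ranked <- st$value$ranked
    note("translation", st$value, st$recomputed, nrow(res$translation))
    say("translation: %s", paste(sprintf("%s NES=%.2f FDR=%.2g",
                                         res$translation$set, res$translation$nes,
                                         res$translation$fdr), collapse = ", "))
  }

  if (want("coverage")) {
    st <- .stage_cache(out_dir, "coverage", FALSE, function() {
      cov <- bundle$coverage
      trs <- cov$transcripts
      x_ko <- vapply(trs, function(t) length(t$ko_centers), integer(1L))
      x_wt <- vapply(trs, function(t) length(t$wt_centers), integer(1L))
      keep <- x_ko + x_wt >= 1L
      bt <- binomial_genotype_test(x_ko[keep], x_wt[keep], cov$depth_ko,
                                   cov$depth_wt,
                                   vapply(trs[keep], `[[`, character(1L), "gene_id"))
      mk_tr <- function(genotype) lapply(trs, function(t)
        list(gene_id = t$gene_id, length = t$length, cds_start = t$cds_start,
             cds_end = t$cds_end,
             centers = if (genotype == "WT") t$wt_centers else t$ko_centers))
      list(binomial = bt,
           metagene_wt = metagene(mk_tr("WT"), cfg$min_reads),
           metagene_ko = metagene(mk_tr("KO"), cfg$min_reads))
    })
    res$coverage <- st$value
    note("coverage", st$value, st$recomputed, nrow(res$coverage$binomial))
    say("coverage: %d transcripts tested, %d with q < 0.05",
        nrow(res$coverage$binomial), sum(res$coverage$binomial$q_value < 0.05))
  }

  if (want("clusters")) {
    if (is.null(res$assignments) && !is.null(res$sites))
      res$assignments <- classify_targets(res$sites, bundle$models,
                                          cfg$annotation_mode)
    if (is.null(res$assignments)) stop_("stage 'clusters' needs stage 'peaks'")
    st <- .stage_cache(out_dir, "clusters", FALSE, function() {
      cl <- kmeans_timecourse(bundle$timecourse, cfg$k, cfg$n_init,
                              seed = derive_seed(cfg$seed, 23L))
      targets <- res$assignments$gene_id[res$assignments$UTR3 | res$assignments$CDS]
      enr <- fisher_cluster_enrichment(cl, targets)
      list(clustering = cl, enrichment = enr,
           summary = summarize_clusters(cl, enr))
    })
    res$clusters <- st$value
    note("clusters", st$value, st$recomputed,
         nrow(res$clusters$enrichment))
    say("clusters: %d clusters, min q = %.2g", cfg$k,
        min(res$clusters$enrichment$q_value))
  }

  res$manifest <- manifest
  res$elapsed <- proc.time()[["elapsed"]] - t0
  if (!is.null(out_dir)) {
    mf <- data.frame(stage = names(manifest$stages),
                     checksum = vapply(manifest$stages, `[[`, character(1L),
                                       "checksum"),
                     recomputed = vapply(manifest$stages, `[[`, logical(1L),
                                         "recomputed"),
                     n = vapply(manifest$stages, function(s)
                       as.integer(s$n %||% NA_integer_), integer(1L)))
    utils::write.table(mf, file.path(out_dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  structure(res, class = "clip_pipeline")
}

#' @export
print.clip_pipeline <- function(x, ...) {
  cat("clip_pipeline run\n")
  if (!is.null(x$sites))
    cat(sprintf("  robust sites: %d (genes with sites: %d)\n", nrow(x$sites),
                length(unique(x$sites$gene_id))))
  if (!is.null(x$records))
    cat(sprintf("  expression: %d/%d genes pass filters\n",
                sum(x$records$pass), nrow(x$records)))
  if (!is.null(x$shift)) {
    cat("  abundance shift (KS vs no-site background):\n")
    for (i in seq_len(nrow(x$shift)))
      cat(sprintf("    %-9s n=%-4d D=%.3f p=%.3g median shift=%+.3f\n",
                  x$shift$class[i], x$shift$n_class[i], x$shift$D[i],
                  x$shift$p_value[i], x$shift$median_shift[i]))
  }
  if (!is.null(x$translation)) {
    cat("  delta-TE enrichment (pre-ranked):\n")
    for (i in seq_len(nrow(x$translation)))
      cat(sprintf("    %-9s ES=%+.3f NES=%+.2f p=%.3g FDR=%.3g\n",
                  x$translation$set[i], x$translation$es[i],
                  x$translation$nes[i], x$translation$p_value[i],
                  x$translation$fdr[i]))
  }
  if (!is.null(x$elapsed)) cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' @export
summary.clip_pipeline <- function(object, ...) {
  print(object)
  if (!is.null(object$clusters)) {
    cat("  cluster enrichment (top rows):\n")
    e <- object$clusters$enrichment
    print(utils::head(e[order(e$p_value), ], 3L), row.names = FALSE)
  }
  invisible(object)
}
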