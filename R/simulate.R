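#' Simulation configuration
#'
#' Defines the synthetic study: gene-model geometry, the target plan
#' (per-gene binding class and peak-height tier), CLIP tag intensities,
#' negative-binomial count models with class-specific genotype effects on
#' abundance and translation efficiency, footprint coverage shapes, and the
#' activation time course.  The default effect structure has 150 3'UTR
#' target genes (abundance effect 0.2 log2 units in the bulk tier, 0 in the
#' top-PH tier; TE effect 0.3 in both), 80 CDS targets (abundance 0.2, TE
#' 0.5), and 60 intron targets with no effects, against a no-site
#' background.
#'
#' @param seed integer global seed; each output artifact derives its own
#'   stream from it (see [derive_seed()]), so adding an artifact never
#'   perturbs existing ones.
#' @param n_genes number of genes.
#' @param classes named integer vector: target genes per binding class.
#' @param top_fraction fraction of each class planted in the top-PH tier.
#' @param delta_abund,delta_te named lists of `c(bulk=, top=)` log2 genotype
#'   effects on RNA abundance and on translation efficiency per class.
#' @param replicates data.frame of CLIP replicates: `replicate`,
#'   `antiserum`.
#' @param lambda_site expected site tags per replicate, `c(bulk=, top=)`.
#' @param lambda_bg_per_kb background tag rate per kb per replicate.
#' @param tag_len CLIP tag length (nt).
#' @param jitter_sd lognormal sd of per-gene-per-replicate site intensity.
#' @param trunc_exact_frac fraction of site tags whose 5' end sits exactly
#'   at the cross-link position (drives CITS detectability).
#' @param n_reps_expr RNA-seq / ribosome-profiling replicates per genotype.
#' @param depth expected library size per expression sample.
#' @param dispersion NB dispersion `phi` (`variance = mu + phi mu^2`).
#' @param abund_sdlog,te_sdlog lognormal sd of baseline abundance and TE.
#' @param cov_depth expected pooled footprint reads per genotype.
#' @param n_timepoints activation time-course length.
#' @param tc_noise_sd per-gene time-course noise sd.
#' @param tc_target_prob probability that a UTR3/CDS target gene follows the
#'   rapidly-induced archetype.
#' @param motif planted AU-rich site motif.
#' @param window_len site sequence-window length.
#' @param downstream downstream extension (nt) used in the gene models.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L,
                       classes = c(UTR3 = 150L, CDS = 80L, intron = 60L),
                       top_fraction = 0.2,
                       delta_abund = list(UTR3 = c(bulk = 0.2, top = 0),
                                          CDS = c(bulk = 0.2, top = 0.2),
                                          intron = c(bulk = 0, top = 0)),
                       delta_te = list(UTR3 = c(bulk = 0.3, top = 0.3),
                                       CDS = c(bulk = 0.5, top = 0.5),
                                       intron = c(bulk = 0, top = 0)),
                       replicates = data.frame(
                         replicate = paste0("r", 1:5),
                         antiserum = c("A", "A", "A", "B", "B")),
                       lambda_site = c(bulk = 10, top = 25),
                       lambda_bg_per_kb = 0.3, tag_len = 35L,
                       jitter_sd = 0.15, trunc_exact_frac = 0.7,
                       n_reps_expr = 4L, depth = 1e6, dispersion = 0.05,
                       abund_sdlog = 1.2, te_sdlog = 0.3,
                       cov_depth = 2e6, n_timepoints = 8L,
                       tc_noise_sd = 0.4, tc_target_prob = 0.6,
                       motif = "UAUUUAUU", window_len = 30L,
                       downstream = 10000L) {
  if (sum(classes) > n_genes) stop_("more target genes than genes")
  if (dispersion <= 0) stop_("dispersion must be > 0")
  if (any(c(lambda_site, lambda_bg_per_kb, depth, cov_depth) < 0))
    stop_("all rates must be >= 0")
  if (!setequal(names(classes), names(delta_abund)) ||
      !setequal(names(classes), names(delta_te)))
    stop_("delta_abund / delta_te must name the same classes as 'classes'")
  structure(as.list(environment()), class = "sim_config")
}

## fixed synthetic gene geometry (nt); all genes share it, strands alternate
.GEOM <- list(utr5 = 200L, cds = 900L, intron = 500L, utr3 = 800L,
              cds_exon1 = 300L, spacing = 15000L)

## gene model + planted-site anchor positions for gene i (1-based)
.synth_gene <- function(i, downstream) {
  g <- .GEOM
  o <- (i - 1L) * g$spacing
  strand <- if (i %% 2L == 1L) "+" else "-"
  if (strand == "+") {
    exons <- rbind(c(o, o + 500L), c(o + 1000L, o + 2400L))
    cds_span <- c(o + 200L, o + 1600L)
    anchors <- c(UTR3 = o + 2000L, CDS = o + 1300L, intron = o + 750L)
  } else {
    exons <- rbind(c(o, o + 1400L), c(o + 1900L, o + 2400L))
    cds_span <- c(o + 800L, o + 2200L)
    anchors <- c(UTR3 = o + 400L, CDS = o + 1100L, intron = o + 1650L)
  }
  gm <- gene_model(sprintf("g%04d", i), "chrS", strand, exons, cds_span, downstream)
  list(gm = gm, anchors = anchors)
}

.ARCHETYPES <- function(T_) {
  t <- seq(0, 1, length.out = T_)
  rbind(early_induced = exp(-((t - 0.15) / 0.18)^2),
        late_induced = t^2,
        transient_mid = exp(-((t - 0.5) / 0.15)^2),
        early_repressed = 1 - exp(-((t - 0.1) / 0.25)^2),
        late_repressed = 1 - t^1.5,
        biphasic = sin(t * 2 * pi) * 0.5 + 0.5)
}

#' Simulate a complete synthetic dataset
#'
#' Generates, from one seeded configuration: gene models; per-replicate CLIP
#' tags (Poisson site tags with per-replicate intensity jitter over a
#' uniform background, truncation positions concentrated at the planted
#' cross-link); RNAseq and ribosome-profiling NB count matrices with
#' class/tier-specific genotype effects (`counts ~ NB(mu 2^(delta g), phi)`,
#' with the ribosome mean additionally scaled by `2^(delta_TE g)`);
#' per-transcript footprint coverage sharing one shape vector between
#' genotypes with magnitude scaled by `2^(delta_TE)`; a clustered activation
#' time course; planted site sequence windows; and a ground-truth table of
#' every planted parameter.  Identical configurations give byte-identical
#' bundles.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `"sim_bundle"`: `models`, `tags`, `rna`, `rp`
#'   ([count_matrix()] objects), `coverage` (per-gene list plus genotype
#'   depths), `timecourse`, `site_windows`, `bg_windows`, `truth`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  ids <- sprintf("g%04d", seq_len(n))

  ## ---- plan (stream 0): baselines, target classes, tiers ----------------
  set.seed(derive_seed(cfg$seed, 0L))
  rel_abund <- stats::rlnorm(n, 0, cfg$abund_sdlog)
  te_base <- stats::rlnorm(n, 0, cfg$te_sdlog)
  class <- rep("none", n); tier <- rep("none", n)
  eligible <- which(rel_abund > stats::quantile(rel_abund, 0.3))
  pick <- sample(eligible, sum(cfg$classes))
  stop_at <- cumsum(cfg$classes)
  for (ci in seq_along(cfg$classes)) {
    sel <- pick[(c(0L, stop_at)[ci] + 1L):stop_at[ci]]
    class[sel] <- names(cfg$classes)[ci]
    n_top <- ceiling(cfg$top_fraction * length(sel))
    tier[sel] <- "bulk"
    tier[sample(sel, n_top)] <- "top"
  }
  d_ab <- numeric(n); d_te <- numeric(n)
  tgt <- class != "none"
  if (any(tgt)) {
    d_ab[tgt] <- mapply(function(cl, tr) cfg$delta_abund[[cl]][[tr]],
                        class[tgt], tier[tgt])
    d_te[tgt] <- mapply(function(cl, tr) cfg$delta_te[[cl]][[tr]],
                        class[tgt], tier[tgt])
  }

  ## ---- gene models (deterministic) ---------------------------------------
  synth <- lapply(seq_len(n), .synth_gene, downstream = cfg$downstream)
  models <- stats::setNames(lapply(synth, `[[`, "gm"), ids)
  anchors <- t(vapply(synth, `[[`, numeric(3L), "anchors"))
  site_center <- ifelse(tgt, anchors[cbind(seq_len(n), match(class, colnames(anchors)))],
                        NA_integer_)

  ## ---- CLIP tags (stream 1) ----------------------------------------------
  set.seed(derive_seed(cfg$seed, 1L))
  L <- cfg$tag_len
  half <- L %/% 2L
  tag_rows <- list()
  for (i in seq_len(n)) {
    gm <- models[[ids[i]]]
    span_kb <- (gm$span[2L] - gm$span[1L]) / 1000
    for (r in seq_len(nrow(cfg$replicates))) {
      starts <- integer(0); is_exact <- logical(0)
      if (tgt[i]) {
        lam <- cfg$lambda_site[[tier[i]]] * stats::rlnorm(1L, 0, cfg$jitter_sd)
        m <- stats::rpois(1L, lam)
        if (m > 0L) {
          exact <- stats::runif(m) < cfg$trunc_exact_frac
          off <- ifelse(exact, half, sample(5:(L - 5L), m, replace = TRUE))
          s <- if (gm$strand == "+") site_center[i] - off
               else site_center[i] + off - L + 1L
          starts <- c(starts, as.integer(s)); is_exact <- c(is_exact, exact)
        }
      }
      m_bg <- stats::rpois(1L, cfg$lambda_bg_per_kb * span_kb)
      if (m_bg > 0L) {
        s <- as.integer(floor(stats::runif(m_bg, gm$span[1L], gm$span[2L] - L)))
        starts <- c(starts, s); is_exact <- c(is_exact, rep(FALSE, m_bg))
      }
      if (length(starts) == 0L) next
      tag_rows[[length(tag_rows) + 1L]] <- data.frame(
        chrom = gm$chrom, start = starts, end = starts + L, strand = gm$strand,
        replicate = cfg$replicates$replicate[r],
        antiserum = cfg$replicates$antiserum[r], gene_id = ids[i])
    }
  }
  tags <- do.call(rbind, tag_rows)
  tags <- clip_tags(tags)

  ## ---- expression counts (streams 2, 3) ----------------------------------
  nb_matrix <- function(base_mu, delta, stream) {
    set.seed(derive_seed(cfg$seed, stream))
    k <- cfg$n_reps_expr
    mu <- cbind(matrix(rep(base_mu, k), ncol = k),
                matrix(rep(base_mu * 2^delta, k), ncol = k))
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                  nrow = n)
    dimnames(cnt) <- list(ids, c(paste0("WT_", seq_len(k)), paste0("KO_", seq_len(k))))
    cnt
  }
  mrna_len <- with(.GEOM, utr5 + cds + utr3)
  lens <- stats::setNames(rep(mrna_len, n), ids)
  meta <- function(assay) data.frame(
    sample = c(paste0("WT_", seq_len(cfg$n_reps_expr)),
               paste0("KO_", seq_len(cfg$n_reps_expr))),
    genotype = rep(c("WT", "KO"), each = cfg$n_reps_expr),
    replicate = rep(seq_len(cfg$n_reps_expr), 2L), assay = assay)
  mu_rna <- rel_abund / sum(rel_abund) * cfg$depth
  rna <- count_matrix(nb_matrix(mu_rna, d_ab, 2L), meta("rnaseq"), lens)
  rel_rp <- rel_abund * te_base
  mu_rp <- rel_rp / sum(rel_rp) * cfg$depth
  rp <- count_matrix(nb_matrix(mu_rp, d_ab + d_te, 3L), meta("riboprof"), lens)

  ## ---- footprint coverage (stream 4) --------------------------------------
  set.seed(derive_seed(cfg$seed, 4L))
  cds_start <- .GEOM$utr5; cds_end <- .GEOM$utr5 + .GEOM$cds
  cov_mu <- rel_rp / sum(rel_rp) * cfg$cov_depth
  coverage <- vector("list", n)
  for (i in seq_len(n)) {
    raw <- stats::rgamma(mrna_len, 2, 1) + 0.05
    shape <- stats::filter(c(raw[1:12], raw, raw[(mrna_len - 11):mrna_len]),
                           rep(1 / 25, 25), sides = 2)
    shape <- as.numeric(shape[13:(mrna_len + 12L)])
    shape[cds_start:(cds_end - 1L) + 1L] <- shape[cds_start:(cds_end - 1L) + 1L] * 3
    shape <- shape / sum(shape)
    n_wt <- stats::rpois(1L, cov_mu[i])
    n_ko <- stats::rpois(1L, cov_mu[i] * 2^d_te[i])
    coverage[[i]] <- list(
      gene_id = ids[i], length = mrna_len, cds_start = cds_start,
      cds_end = cds_end, shape = shape,
      wt_centers = sample.int(mrna_len, n_wt, replace = TRUE, prob = shape) - 1L,
      ko_centers = sample.int(mrna_len, n_ko, replace = TRUE, prob = shape) - 1L)
  }
  names(coverage) <- ids
  coverage <- list(transcripts = coverage,
                   depth_wt = sum(vapply(coverage, function(x)
                     length(x$wt_centers), integer(1L))),
                   depth_ko = sum(vapply(coverage, function(x)
                     length(x$ko_centers), integer(1L))))

  ## ---- activation time course (stream 5) ----------------------------------
  set.seed(derive_seed(cfg$seed, 5L))
  arch <- .ARCHETYPES(cfg$n_timepoints)
  archetype <- integer(n)
  fast <- class %in% c("UTR3", "CDS") & stats::runif(n) < cfg$tc_target_prob
  archetype[fast] <- 1L
  archetype[!fast] <- sample.int(nrow(arch), sum(!fast), replace = TRUE)
  timecourse <- arch[archetype, , drop = FALSE] +
    matrix(stats::rnorm(n * cfg$n_timepoints, 0, cfg$tc_noise_sd), nrow = n)
  dimnames(timecourse) <- list(ids, paste0("t", seq_len(cfg$n_timepoints) - 1L))

  ## ---- site sequence windows (stream 6) ------------------------------------
  set.seed(derive_seed(cfg$seed, 6L))
  wl <- cfg$window_len
  mot <- strsplit(chartr("T", "U", toupper(cfg$motif)), "")[[1L]]
  mk_window <- function(plant) {
    s <- sample(c("A", "C", "G", "U"), wl, replace = TRUE)
    if (plant) {
      at <- (wl - length(mot)) %/% 2L
      s[(at + 1L):(at + length(mot))] <- mot
    }
    paste(s, collapse = "")
  }
  site_windows <- stats::setNames(vapply(which(tgt), function(i) mk_window(TRUE),
                                         character(1L)), ids[tgt])
  bg_windows <- vapply(seq_len(200L), function(i) mk_window(FALSE), character(1L))

  truth <- data.frame(gene_id = ids, class = class, tier = tier,
                      delta_abund = d_ab, delta_te = d_te,
                      site_center = site_center,
                      lambda_site = ifelse(tgt, cfg$lambda_site[
                        ifelse(tier == "none", "bulk", tier)], 0),
                      rel_abund = rel_abund, te_base = te_base,
                      archetype = rownames(arch)[archetype])

  structure(list(models = models, tags = tags, rna = rna, rp = rp,
                 coverage = coverage, timecourse = timecourse,
                 site_windows = site_windows, bg_windows = bg_windows,
                 truth = truth, cfg = cfg),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("sim_bundle: %d genes (%d targets), %d CLIP tags, seed %d\n",
              nrow(x$truth), sum(x$truth$class != "none"), nrow(x$tags),
              x$cfg$seed))
  invisible(x)
}

## ---- fixture writing and reading ----------------------------------------

#' Write a simulated bundle to plain-text fixture files
#'
#' BED6 tag files (one per replicate; name field `replicate:antiserum`; the
#' 5' end of each interval is the truncation position), BED12 gene models,
#' and TSV count/metadata/length/time-course/truth tables.  Files round-trip
#' losslessly through the package readers.
#'
#' @param bundle a [simulate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name, col.names = TRUE) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = col.names)
    paths[name] <<- p
    p
  }
  for (r in unique(bundle$tags$replicate)) {
    tg <- bundle$tags[bundle$tags$replicate == r, , drop = FALSE]
    w(data.frame(tg$chrom, tg$start, tg$end,
                 paste(tg$replicate, tg$antiserum, sep = ":"), 0L, tg$strand),
      sprintf("tags_%s.bed", r), col.names = FALSE)
  }
  write_gene_models_bed12(bundle$models, file.path(outdir, "genes.bed"))
  paths[["genes.bed"]] <- file.path(outdir, "genes.bed")
  cm_files <- function(cm, prefix) {
    w(data.frame(gene_id = rownames(cm$counts), cm$counts, check.names = FALSE),
      sprintf("%s_counts.tsv", prefix))
    w(cm$meta, sprintf("%s_meta.tsv", prefix))
  }
  cm_files(bundle$rna, "rna"); cm_files(bundle$rp, "rp")
  w(data.frame(gene_id = names(bundle$rna$lengths), length = bundle$rna$lengths),
    "lengths.tsv")
  w(data.frame(gene_id = rownames(bundle$timecourse), bundle$timecourse,
               check.names = FALSE), "timecourse.tsv")
  w(bundle$truth, "truth.tsv")
  invisible(unlist(paths))
}

#' Write gene models as BED12
#'
#' @param models named list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(models, path) {
  lines <- vapply(models, function(gm) {
    ex <- gm$exons
    thick <- if (gm$coding) {
      all_cds <- gm$cds
      c(min(all_cds[, 1L]), max(all_cds[, 2L]))
    } else c(gm$tx_start, gm$tx_start)
    paste(gm$chrom, gm$tx_start, gm$tx_end, gm$gene_id, 0L, gm$strand,
          thick[1L], thick[2L], "0", nrow(ex),
          paste(ex[, 2L] - ex[, 1L], collapse = ","),
          paste(ex[, 1L] - gm$tx_start, collapse = ","), sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read CLIP tags from BED6 files
#'
#' The BED name field must be `replicate:antiserum`; truncation positions
#' are derived from the 5' end of each interval.
#'
#' @param paths one or more BED6 files.
#' @return a validated CLIP tag table (see [clip_tags()]).
#' @export
read_clip_tags <- function(paths) {
  tabs <- lapply(paths, function(p) {
    df <- utils::read.delim(p, header = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand"))
    ra <- strsplit(df$name, ":", fixed = TRUE)
    bad <- which(lengths(ra) != 2L)
    if (length(bad))
      stop_("%s: line %d name field is not 'replicate:antiserum'", p, bad[1L])
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               strand = df$strand,
               replicate = vapply(ra, `[[`, character(1L), 1L),
               antiserum = vapply(ra, `[[`, character(1L), 2L))
  })
  clip_tags(do.call(rbind, tabs))
}

#' Read a count matrix from TSV files
#'
#' @param counts_path TSV with `gene_id` column then one column per sample.
#' @param meta_path TSV with `sample`, `genotype`, `replicate`, `assay`.
#' @param lengths_path TSV with `gene_id`, `length`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, meta_path, lengths_path) {
  cnt <- utils::read.delim(counts_path, check.names = FALSE)
  mat <- as.matrix(cnt[, -1L, drop = FALSE])
  rownames(mat) <- cnt$gene_id
  meta <- utils::read.delim(meta_path)
  lens <- utils::read.delim(lengths_path)
  count_matrix(mat, meta, stats::setNames(lens$length, lens$gene_id))
}
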