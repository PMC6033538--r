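#' CLIP tag table constructor
#'
#' Normalizes a table of aligned CLIP tag intervals.  Each tag carries its
#' replicate and antiserum provenance and the genomic coordinate of its 5'
#' end (the reverse-transcription truncation position): `start` on the plus
#' strand, `end - 1` on the minus strand.  If a `truncation` column is absent
#' it is derived; if present it is validated.
#'
#' @param tags data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `replicate`, `antiserum` and optionally `truncation`.
#' @return the validated data.frame.
#' @export
clip_tags <- function(tags) {
  need <- c("chrom", "start", "end", "strand", "replicate", "antiserum")
  miss <- setdiff(need, names(tags))
  if (length(miss)) stop_("tags missing column(s): %s", paste(miss, collapse = ", "))
  if (any(tags$end <= tags$start)) stop_("tag with non-positive length")
  if (!all(tags$strand %in% c("+", "-"))) stop_("tag strand must be '+' or '-'")
  if (any(is.na(tags$replicate)) || any(is.na(tags$antiserum)) ||
      any(!nzchar(tags$antiserum)))
    stop_("every tag needs replicate and antiserum labels")
  tr <- ifelse(tags$strand == "+", tags$start, tags$end - 1L)
  if (is.null(tags$truncation)) tags$truncation <- as.integer(tr)
  else if (!all(tags$truncation == tr))
    stop_("truncation position must equal the 5' end of the tag interval")
  tags
}

#' Per-base pileup depth over a gene's extended span
#'
#' @param tags CLIP tag table (see [clip_tags()]); only tags on `gm`'s
#'   chromosome and strand that overlap the extended span contribute; tags
#'   entirely outside it are dropped (their number is recorded in the
#'   `"n_excluded"` attribute and a warning is emitted).
#' @param gm a [gene_model()].
#' @return integer depth vector over `[gm$span[1], gm$span[2])`, with
#'   attributes `offset` (genomic coordinate of element 1) and `n_excluded`.
#' @export
pileup <- function(tags, gm) {
  sp0 <- gm$span[1L]; sp1 <- gm$span[2L]
  on_gene <- tags$chrom == gm$chrom & tags$strand == gm$strand
  inside <- on_gene & tags$start < sp1 & tags$end > sp0
  n_excl <- sum(on_gene) - sum(inside)
  if (n_excl > 0L)
    warning(sprintf("%d tag(s) outside extended span of %s excluded", n_excl, gm$gene_id))
  w <- sp1 - sp0
  d <- integer(w + 1L)
  if (any(inside)) {
    s <- pmax(tags$start[inside], sp0) - sp0 + 1L
    e <- pmin(tags$end[inside], sp1) - sp0 + 1L
    agg <- tapply(rep(1L, length(s)), s, sum); d[as.integer(names(agg))] <- agg
    agg <- tapply(rep(1L, length(e)), e, sum)
    idx <- as.integer(names(agg))
    d[idx] <- d[idx] - agg
  }
  out <- cumsum(d)[seq_len(w)]
  attr(out, "offset") <- sp0
  attr(out, "n_excluded") <- n_excl
  out
}

## ---- candidate peak detection (segment representation, O(m log m)) ------

## Segment representation of a pileup: breakpoints at tag starts/ends.
## Returns list(pos = segment starts (0-based genomic), len, depth).
.depth_segments <- function(starts, ends) {
  bp <- sort(unique(c(starts, ends)))
  k <- length(bp)
  if (k == 0L) return(list(pos = integer(0), len = integer(0), depth = integer(0)))
  ## depth on [bp[i], bp[i+1]) = #starts <= bp[i] - #ends <= bp[i]
  d <- findInterval(bp[-k], sort(starts)) - findInterval(bp[-k], sort(ends))
  list(pos = bp[-k], len = diff(bp), depth = d)
}

## Candidate peaks: maximal runs of positive depth, split at internal valleys
## whose depth falls below 50% of the smaller flanking local maximum.
## Returns list(start, end, ph) vectors in genomic coordinates (0-based);
## kept as plain vectors because this sits in the permutation hot loop.
.candidate_peaks <- function(seg) {
  d <- seg$depth
  if (length(d) == 0L || !any(d > 0L)) {
    return(list(start = integer(0), end = integer(0), ph = integer(0)))
  }
  out_s <- integer(0); out_e <- integer(0); out_h <- integer(0)
  r <- rle(d > 0L)
  ends_idx <- cumsum(r$lengths); starts_idx <- ends_idx - r$lengths + 1L
  for (j in which(r$values)) {
    idx <- starts_idx[j]:ends_idx[j]
    dd <- d[idx]
    ## local maxima over the run's segment sequence (plateau-aware)
    n <- length(dd)
    seg_start <- 1L           # index (within run) where current peak starts
    H <- dd[1L]               # max depth of current peak
    vmin <- Inf; vpos <- NA_integer_
    splits <- integer(0)      # split boundaries: first segment of right peak
    if (n > 1L) for (i in 2:n) {
      if (dd[i] < vmin && dd[i] < H) { vmin <- dd[i]; vpos <- i }
      if (dd[i] > dd[i - 1L]) {
        ## rising after a valley: check split condition vs forthcoming max
        rest_max <- max(dd[i:n])
        if (is.finite(vmin) && vmin < 0.5 * min(H, rest_max)) {
          splits <- c(splits, vpos + 1L)    # valley min segment ends left peak
          H <- dd[i]; vmin <- Inf; vpos <- NA_integer_
        } else {
          H <- max(H, dd[i])
          if (dd[i] >= H) { vmin <- Inf; vpos <- NA_integer_ }
        }
      }
    }
    bounds <- c(1L, splits, n + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      ii <- idx[bounds[b]:(bounds[b + 1L] - 1L)]
      out_s <- c(out_s, seg$pos[ii[1L]])
      out_e <- c(out_e, seg$pos[ii[length(ii)]] + seg$len[ii[length(ii)]])
      out_h <- c(out_h, max(d[ii]))
    }
  }
  list(start = out_s, end = out_e, ph = out_h)
}

## expected number of null candidate peaks with PH >= h (vector over h=1..hmax)
## under uniform re-placement of m tags of the given lengths over a span
.null_peak_expectation <- function(lens, span_w, n_perm, hmax) {
  counts <- numeric(hmax)
  m <- length(lens)
  for (b in seq_len(n_perm)) {
    s <- as.integer(floor(stats::runif(m, 0, pmax(1L, span_w - lens + 1L))))
    o <- order(s)
    ss <- s[o]; ee <- ss + lens[o]
    if (m == 1L || all(ee[-m] <= ss[-1L])) {
      counts[1L] <- counts[1L] + m     # disjoint tags: m singleton peaks
      next
    }
    cand <- .candidate_peaks(.depth_segments(s, s + lens))
    if (length(cand$ph)) {
      tb <- tabulate(pmin(cand$ph, hmax), nbins = hmax)
      counts <- counts + tb
    }
  }
  rev(cumsum(rev(counts))) / n_perm
}

#' Call CLIP peaks on one gene with a permutation FDR
#'
#' Candidate peaks are maximal runs of positive pileup depth, split at
#' internal valleys falling below 50% of the smaller flanking local maximum.
#' The null model re-places the gene's tags uniformly over the extended gene
#' span (annotated transcript plus downstream extension) `n_perm` times;
#' `FDR(h) = E[null candidate peaks with PH >= h] / #observed candidates with
#' PH >= h`, monotonized to be non-increasing in peak height.  Candidates
#' with `FDR <= alpha` are returned with their tag support sets.
#'
#' @param tags CLIP tag table for this gene (any replicate mix).
#' @param gm a [gene_model()].
#' @param alpha FDR threshold (default 0.01).
#' @param n_perm number of permutations (>= 20; should be at least `2/alpha`
#'   so the null tail expectation is resolved at the call boundary).
#' @param null_cache optional environment used to memoize the permutation
#'   null across genes with identical tag count, tag lengths and span width
#'   (a large speedup on simulated datasets with a shared gene structure).
#' @return data.frame of peaks: `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `ph`, `n_tags`, `fdr`, plus list-columns `replicates` and
#'   `antisera` with the supporting label sets.
#' @export
call_peaks <- function(tags, gm, alpha = 0.01, n_perm = 200L, null_cache = NULL) {
  if (n_perm < 20L) stop_("n_perm must be >= 20 for a stable FDR estimate")
  sp0 <- gm$span[1L]; sp1 <- gm$span[2L]
  keep <- tags$chrom == gm$chrom & tags$strand == gm$strand &
    tags$start >= sp0 & tags$end <= sp1
  tags <- tags[keep, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), gene_id = character(0),
                      ph = integer(0), n_tags = integer(0), fdr = numeric(0))
  empty$replicates <- list(); empty$antisera <- list()
  if (nrow(tags) == 0L) return(empty)

  cand <- .candidate_peaks(.depth_segments(tags$start, tags$end))
  if (length(cand$ph) == 0L) return(empty)
  hmax <- max(cand$ph)
  lens <- sort(tags$end - tags$start)
  key <- paste(sp1 - sp0, paste(lens, collapse = ","), sep = "|")
  if (!is.null(null_cache) && !is.null(null_cache[[key]]) &&
      length(null_cache[[key]]) >= hmax) {
    e_null <- null_cache[[key]]
  } else {
    e_null <- .null_peak_expectation(lens, sp1 - sp0, n_perm, max(hmax, 10L))
    if (!is.null(null_cache)) null_cache[[key]] <- e_null
  }
  obs_ge <- vapply(seq_len(hmax), function(h) sum(cand$ph >= h), numeric(1L))
  fdr <- pmin(1, e_null[seq_len(hmax)] / obs_ge)
  ## monotonize: FDR non-increasing in h (conservative, right-to-left max)
  if (hmax > 1L) for (h in (hmax - 1L):1L) fdr[h] <- max(fdr[h], fdr[h + 1L])
  keep_i <- which(fdr[cand$ph] <= alpha)
  if (length(keep_i) == 0L) return(empty)
  cand <- list(start = cand$start[keep_i], end = cand$end[keep_i],
               ph = cand$ph[keep_i], fdr = fdr[cand$ph[keep_i]])

  n_cand <- length(cand$ph)
  sup_r <- vector("list", n_cand); sup_a <- vector("list", n_cand)
  n_tags <- integer(n_cand)
  for (i in seq_len(n_cand)) {
    ov <- tags$start < cand$end[i] & tags$end > cand$start[i]
    n_tags[i] <- sum(ov)
    sup_r[[i]] <- sort(unique(tags$replicate[ov]))
    sup_a[[i]] <- sort(unique(tags$antiserum[ov]))
  }
  out <- data.frame(chrom = gm$chrom, start = cand$start, end = cand$end,
                    strand = gm$strand, gene_id = gm$gene_id, ph = cand$ph,
                    n_tags = n_tags, fdr = cand$fdr)
  out$replicates <- sup_r
  out$antisera <- sup_a
  out
}

## Assign each tag to every gene whose extended span fully contains it
## (strand-aware).  Uses a findInterval sweep when the spans on a strand are
## non-overlapping; falls back to per-gene scans otherwise (overlapping
## genes: a tag is assigned to all of them).  Returns a list of tag tables
## keyed by gene_id.
.assign_tags_to_genes <- function(tags, models) {
  out <- list()
  strands <- vapply(models, `[[`, character(1L), "strand")
  chroms <- vapply(models, `[[`, character(1L), "chrom")
  for (str in unique(strands)) for (chr in unique(chroms)) {
    ms <- models[strands == str & chroms == chr]
    if (length(ms) == 0L) next
    tt <- tags[tags$strand == str & tags$chrom == chr, , drop = FALSE]
    if (nrow(tt) == 0L) next
    sp <- t(vapply(ms, `[[`, integer(2L), "span"))
    o <- order(sp[, 1L])
    sp <- sp[o, , drop = FALSE]; ms <- ms[o]
    if (length(ms) == 1L || all(sp[-1L, 1L] >= sp[-nrow(sp), 2L])) {
      gi <- findInterval(tt$start, sp[, 1L])
      ok <- gi >= 1L & tt$start >= sp[pmax(gi, 1L), 1L] &
        tt$end <= sp[pmax(gi, 1L), 2L]
      parts <- split(tt[ok, , drop = FALSE], gi[ok])
      names(parts) <- vapply(ms[as.integer(names(parts))], `[[`,
                             character(1L), "gene_id")
      out <- c(out, parts)
    } else {
      for (gm in ms) {
        sel <- tt$start >= gm$span[1L] & tt$end <= gm$span[2L]
        if (any(sel))
          out[[gm$gene_id]] <- rbind(out[[gm$gene_id]], tt[sel, , drop = FALSE])
      }
    }
  }
  out
}

#' Call peaks across a whole dataset
#'
#' Assigns tags to genes by extended-span overlap (strand-aware; a tag
#' overlapping several genes is assigned to each and counted once per gene),
#' then calls peaks per gene, per replicate (`mode = "per_replicate"`) or on
#' all tags pooled (`mode = "pooled"`), sharing one permutation-null cache.
#'
#' @param tags CLIP tag table for the dataset.
#' @param models named list of [gene_model()] objects.
#' @param mode `"per_replicate"` or `"pooled"`.
#' @inheritParams call_peaks
#' @return data.frame of peaks across genes (same columns as [call_peaks()]).
#' @export
call_peaks_all <- function(tags, models, mode = c("per_replicate", "pooled"),
                           alpha = 0.01, n_perm = 200L) {
  mode <- match.arg(mode)
  cache <- new.env(parent = emptyenv())
  tags_by_gene <- .assign_tags_to_genes(tags, models)
  res <- vector("list", length(models))
  for (gi in seq_along(models)) {
    gm <- models[[gi]]
    gt <- tags_by_gene[[gm$gene_id]]
    if (is.null(gt) || nrow(gt) == 0L) next
    if (mode == "pooled") {
      res[[gi]] <- call_peaks(gt, gm, alpha, n_perm, cache)
    } else {
      res[[gi]] <- do.call(rbind, lapply(split(gt, gt$replicate), function(x)
        call_peaks(x, gm, alpha, n_perm, cache)))
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(out)) {
    out <- call_peaks(clip_tags(data.frame(chrom = character(0), start = integer(0),
                                           end = integer(0), strand = character(0),
                                           replicate = character(0),
                                           antiserum = character(0))),
                      models[[1L]], alpha, n_perm)
  }
  rownames(out) <- NULL
  out
}

#' Define robust binding sites from replicate peak sets
#'
#' Merges peaks that overlap by at least 1 bp (same gene and strand) into
#' union-interval sites, takes the site peak height as the maximum
#' constituent PH, unions the replicate/antiserum support sets, and keeps
#' sites satisfying all of: `PH > min_ph` (strict), at least `min_replicates`
#' supporting biological replicates, and at least `min_antisera` distinct
#' antisera.  The `"pooled"` preset applies the thresholds used for
#' pooled-tag peak sets (support from more than 5 replicates, read strictly
#' as >= 6, and 2 antisera).
#'
#' @param peaks peak table from [call_peaks()] / [call_peaks_all()].
#' @param min_ph strict peak-height threshold (default 5: PH must exceed it).
#' @param min_replicates minimum number of supporting biological replicates.
#' @param min_antisera minimum number of distinct antisera.
#' @param mode threshold preset; `"pooled"` raises `min_replicates` to 6
#'   unless given explicitly.
#' @return data.frame of robust sites: interval columns, `gene_id`, `ph`,
#'   `n_tags`, `n_replicates`, `n_antisera`, `site_id`, and list-columns
#'   `replicates`, `antisera`.
#' @export
define_robust_sites <- function(peaks, min_ph = 5L, min_replicates = NULL,
                                min_antisera = 2L,
                                mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  if (is.null(min_replicates)) min_replicates <- if (mode == "pooled") 6L else 3L
  if (any(lengths(peaks$antisera) == 0L))
    stop_("peak without antiserum label")
  if (nrow(peaks) == 0L) {
    out <- peaks
    out$site_id <- character(0)
    return(out)
  }
  rows <- list()
  for (g in split(seq_len(nrow(peaks)), paste(peaks$gene_id, peaks$strand))) {
    p <- peaks[g, , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    cur <- 1L; s <- p$start[1L]; e <- p$end[1L]; members <- 1L
    flush <- function(s, e, members) {
      list(chrom = p$chrom[1L], start = s, end = e, strand = p$strand[1L],
           gene_id = p$gene_id[1L], ph = max(p$ph[members]),
           n_tags = sum(p$n_tags[members]),
           replicates = list(sort(unique(unlist(p$replicates[members])))),
           antisera = list(sort(unique(unlist(p$antisera[members])))))
    }
    if (nrow(p) > 1L) for (i in 2:nrow(p)) {
      if (p$start[i] < e) { e <- max(e, p$end[i]); members <- c(members, i) }
      else { rows[[length(rows) + 1L]] <- flush(s, e, members)
             s <- p$start[i]; e <- p$end[i]; members <- i }
    }
    rows[[length(rows) + 1L]] <- flush(s, e, members)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    df <- data.frame(chrom = r$chrom, start = r$start, end = r$end,
                     strand = r$strand, gene_id = r$gene_id, ph = r$ph,
                     n_tags = r$n_tags)
    df$replicates <- r$replicates; df$antisera <- r$antisera
    df
  }))
  out$n_replicates <- lengths(out$replicates)
  out$n_antisera <- lengths(out$antisera)
  keep <- out$ph > min_ph & out$n_replicates >= min_replicates &
    out$n_antisera >= min_antisera
  out <- out[keep, , drop = FALSE]
  out$site_id <- sprintf("%s:%d-%d", out$gene_id, out$start, out$end)
  rownames(out) <- NULL
  out
}

#' Stratify robust sites into top/bulk tiers by peak height
#'
#' Sites are ranked by PH descending, ties broken by `n_tags` descending and
#' then lexicographic `site_id`, and the top `ceiling(top_fraction * N)` are
#' labelled `"top"`.  With `scope = "per_region"` (default) the ranking is
#' within each site's highest-precedence region label; `"global"` ranks all
#' sites together.
#'
#' @param sites robust-site table; for `per_region` scope it must carry a
#'   `region` column (see [annotate_sites()]).
#' @param top_fraction fraction labelled `"top"` (default 0.20).
#' @param scope `"per_region"` or `"global"`.
#' @return `sites` with a `tier` column.
#' @export
stratify_by_ph <- function(sites, top_fraction = 0.20,
                           scope = c("per_region", "global")) {
  scope <- match.arg(scope)
  if (nrow(sites) == 0L) stop_("no sites to stratify")
  tier_one <- function(idx) {
    o <- idx[order(-sites$ph[idx], -sites$n_tags[idx], sites$site_id[idx])]
    n_top <- ceiling(top_fraction * length(o))
    tier <- rep("bulk", length(o)); tier[seq_len(n_top)] <- "top"
    tier[match(idx, o)]
  }
  sites$tier <- "bulk"
  if (scope == "global") {
    sites$tier <- tier_one(seq_len(nrow(sites)))
  } else {
    if (is.null(sites$region)) stop_("per_region scope needs a 'region' column")
    for (idx in split(seq_len(nrow(sites)), sites$region))
      sites$tier[idx] <- tier_one(idx)
  }
  sites
}

#' Annotate sites with transcript-region labels
#'
#' Adds `region` (single highest-precedence label) and a list-column
#' `regions` (all overlapped labels) to a site or peak table.
#'
#' @param sites site/peak table with `chrom`, `start`, `end`, `strand`,
#'   `gene_id`.
#' @param models named list of [gene_model()] objects.
#' @return `sites` with `region` and `regions` columns.
#' @export
annotate_sites <- function(sites, models) {
  if (nrow(sites) == 0L) { sites$region <- character(0); sites$regions <- list(); return(sites) }
  regs <- vector("list", nrow(sites))
  reg1 <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    gm <- models[[sites$gene_id[i]]]
    if (is.null(gm)) stop_("site references unknown gene '%s'", sites$gene_id[i])
    iv <- ginterval(sites$chrom[i], sites$start[i], sites$end[i], sites$strand[i])
    regs[[i]] <- assign_region(iv, gm, "non_exclusive")
    reg1[i] <- assign_region(iv, gm, "exclusive")
  }
  sites$region <- reg1
  sites$regions <- regs
  sites
}

#' Cross-link-induced truncation sites within peaks
#'
#' Within each peak of width `w` containing `m` tag truncation positions,
#' every position carrying at least one truncation is tested for excess 5'
#' ends against `Binomial(m, 1/w)` (upper tail); Benjamini-Hochberg
#' correction is applied across all tested positions, and positions with
#' `q <= alpha` are reported.  Replicates are meant to be pooled upstream.
#'
#' @param tags pooled CLIP tag table with `truncation` positions.
#' @param peaks peak or robust-site table.
#' @param alpha q-value threshold (default 0.05).
#' @return data.frame: `chrom`, `position`, `strand`, `gene_id`, `peak_id`,
#'   `truncation_count`, `n_truncations`, `p_value`, `q_value`.
#' @export
call_cits <- function(tags, peaks, alpha = 0.05) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    w <- peaks$end[i] - peaks$start[i]
    sel <- tags$chrom == peaks$chrom[i] & tags$strand == peaks$strand[i] &
      tags$truncation >= peaks$start[i] & tags$truncation < peaks$end[i]
    m <- sum(sel)
    if (m == 0L) next
    tab <- table(tags$truncation[sel])
    pos <- as.integer(names(tab)); cnt <- as.integer(tab)
    p <- stats::pbinom(cnt - 1L, m, 1 / w, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = peaks$chrom[i], position = pos, strand = peaks$strand[i],
      gene_id = peaks$gene_id[i],
      peak_id = sprintf("%s:%d-%d", peaks$gene_id[i], peaks$start[i], peaks$end[i]),
      truncation_count = cnt, n_truncations = m, p_value = p)
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), position = integer(0),
                      strand = character(0), gene_id = character(0),
                      peak_id = character(0), truncation_count = integer(0),
                      n_truncations = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out <- out[out$q_value <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}
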