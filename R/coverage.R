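## Ribosome-footprint coverage along transcripts.  "Coverage" throughout
## counts read centers (the midpoint of each footprint interval), matching
## the per-position proportion logic of the metagene profile.

#' Sliding-window depth-normalized coverage profile
#'
#' Window value = (number of read centers in `[i, i + w)`) / library_size
#' x 10^6, i.e. reads per window per million mapped.  Step 1 by default.
#'
#' @param centers integer vector of read-center positions (0-based,
#'   transcript coordinates).
#' @param length transcript length (nt).
#' @param library_size total mapped reads in the dataset.
#' @param w window length (default 20).
#' @param step window step (default 1).
#' @return data.frame: `start` (0-based window start), `value`.  Empty (with
#'   a warning) when `length < w`.
#' @export
window_coverage <- function(centers, length, library_size, w = 20L, step = 1L) {
  if (library_size <= 0) stop_("library_size must be > 0")
  if (length < w) {
    warning("transcript shorter than window; empty profile")
    return(data.frame(start = integer(0), value = numeric(0)))
  }
  if (any(centers < 0L | centers >= length)) stop_("read center outside transcript")
  cnt <- tabulate(centers + 1L, nbins = length)
  cs <- c(0, cumsum(cnt))
  starts <- seq.int(0L, length - w, by = step)
  vals <- (cs[starts + w + 1L] - cs[starts + 1L]) / library_size * 1e6
  data.frame(start = starts, value = vals)
}

#' Per-transcript binomial test of genotype coverage difference
#'
#' For each transcript, the KO read count is tested against
#' `Binomial(n = x_ko + x_wt, p0 = depth_ko / (depth_ko + depth_wt))`, the
#' null being that coverage splits between genotypes in proportion to
#' sequencing depth.  Two-sided p-values use the exact minimum-likelihood
#' method ([stats::binom.test()]); Benjamini-Hochberg q-values are computed
#' across transcripts.
#'
#' @param x_ko,x_wt integer vectors of per-transcript read counts.
#' @param depth_ko,depth_wt total mapped reads per genotype dataset.
#' @param gene_id optional transcript/gene identifiers.
#' @return data.frame: `gene_id`, `x_ko`, `n`, `p0`, `p_value`, `q_value`.
#' @export
binomial_genotype_test <- function(x_ko, x_wt, depth_ko, depth_wt,
                                   gene_id = NULL) {
  if (depth_ko <= 0 || depth_wt <= 0) stop_("genotype depths must be > 0")
  n <- x_ko + x_wt
  if (any(n < 1L)) stop_("transcript with zero reads in both genotypes")
  p0 <- depth_ko / (depth_ko + depth_wt)
  p <- vapply(seq_along(n), function(i)
    stats::binom.test(x_ko[i], n[i], p0)$p.value, numeric(1L))
  data.frame(gene_id = gene_id %||% sprintf("t%d", seq_along(n)),
             x_ko = x_ko, n = n, p0 = p0, p_value = p,
             q_value = stats::p.adjust(p, "BH"))
}

## map transcript positions to (segment, position) metagene coordinates.
## cds: [cds_start, cds_end).  flank nt at each CDS end stay nt-resolved;
## the CDS middle is scaled into mid_bins bins.
.metagene_coord <- function(pos, cds_start, cds_end, anchor, flank, mid_bins) {
  seg <- character(length(pos)); out <- integer(length(pos))
  if (anchor == "start") {
    seg[] <- "start"; out <- pos - cds_start
  } else if (anchor == "stop") {
    seg[] <- "stop"; out <- pos - cds_end
  } else {
    cds_len <- cds_end - cds_start
    fl <- min(flank, cds_len %/% 2L)
    utr5 <- pos < cds_start
    utr3 <- pos >= cds_end
    s_fl <- !utr5 & !utr3 & (pos - cds_start) < fl
    e_fl <- !utr5 & !utr3 & (cds_end - pos) <= fl & !s_fl
    mid <- !utr5 & !utr3 & !s_fl & !e_fl
    seg[utr5] <- "utr5";       out[utr5] <- pos[utr5] - cds_start
    seg[s_fl] <- "cds_start";  out[s_fl] <- pos[s_fl] - cds_start
    seg[e_fl] <- "cds_stop";   out[e_fl] <- pos[e_fl] - cds_end
    seg[utr3] <- "utr3";       out[utr3] <- pos[utr3] - cds_end
    if (any(mid)) {
      rel <- (pos[mid] - cds_start - fl) / pmax(1L, cds_len - 2L * fl)
      seg[mid] <- "cds_mid"
      out[mid] <- pmin(mid_bins - 1L, as.integer(floor(rel * mid_bins)))
    }
  }
  data.frame(segment = seg, position = out)
}

#' Metagene footprint-coverage profile
#'
#' Transcripts with at least `min_reads` read centers in the region of
#' interest are converted to per-position read proportions (each
#' transcript's proportion vector sums to 1) and averaged position-wise
#' over the transcripts contributing at that position.  Positions are
#' anchored to the coding region: `anchor = "both"` (default) reports
#' nucleotide-resolved positions around the CDS start and stop with the CDS
#' middle scaled into `mid_bins` bins; `"start"`/`"stop"` use a single
#' anchor.
#'
#' @param transcripts list; each element a list with `gene_id`, `centers`
#'   (0-based transcript positions), `length`, `cds_start`, `cds_end`.
#' @param min_reads minimum read count in the region of interest
#'   (default 10).
#' @param anchor `"both"`, `"start"` or `"stop"`.
#' @param roi region of interest for the read filter: `"cds"` (default) or
#'   `"transcript"`.
#' @param flank nt kept at nucleotide resolution at each CDS end
#'   (`anchor = "both"`).
#' @param mid_bins number of bins for the scaled CDS middle.
#' @return data.frame: `segment`, `position`, `mean_proportion`,
#'   `n_transcripts`.  Empty, with a warning, if no transcript qualifies.
#' @export
metagene <- function(transcripts, min_reads = 10L,
                     anchor = c("both", "start", "stop"), roi = c("cds", "transcript"),
                     flank = 50L, mid_bins = 100L) {
  anchor <- match.arg(anchor); roi <- match.arg(roi)
  acc <- new.env(parent = emptyenv())
  acc$sum <- numeric(0); acc$n <- integer(0); acc$key <- character(0)
  n_used <- 0L
  for (tr in transcripts) {
    cen <- tr$centers
    n_roi <- if (roi == "cds") sum(cen >= tr$cds_start & cen < tr$cds_end)
             else length(cen)
    if (n_roi < min_reads) next
    n_used <- n_used + 1L
    ## full per-position proportion vector (zeros included: a transcript is
    ## "represented" at every position its extent covers, reads or not)
    cnt <- tabulate(cen + 1L, nbins = tr$length)
    mc <- .metagene_coord(0:(tr$length - 1L), tr$cds_start, tr$cds_end,
                          anchor, flank, mid_bins)
    key_all <- paste(mc$segment, mc$position)
    pr <- rowsum(cnt / length(cen), key_all)         # sums to 1 per transcript
    key <- rownames(pr)
    new <- !(key %in% acc$key)
    if (any(new)) {
      acc$key <- c(acc$key, key[new])
      acc$sum <- c(acc$sum, numeric(sum(new)))
      acc$n <- c(acc$n, integer(sum(new)))
    }
    ix <- match(key, acc$key)
    acc$sum[ix] <- acc$sum[ix] + pr[, 1L]
    acc$n[ix] <- acc$n[ix] + 1L
  }
  if (n_used == 0L) {
    warning("no transcript passes the read filter; empty metagene")
    return(data.frame(segment = character(0), position = integer(0),
                      mean_proportion = numeric(0), n_transcripts = integer(0)))
  }
  parts <- strsplit(acc$key, " ", fixed = TRUE)
  out <- data.frame(segment = vapply(parts, `[[`, character(1L), 1L),
                    position = as.integer(vapply(parts, `[[`, character(1L), 2L)),
                    mean_proportion = acc$sum / acc$n, n_transcripts = acc$n)
  seg_order <- c("utr5", "cds_start", "cds_mid", "cds_stop", "utr3", "start", "stop")
  out <- out[order(match(out$segment, seg_order), out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
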