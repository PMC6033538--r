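#' Genomic interval
#'
#' A minimal stranded interval in the package-wide 0-based half-open
#' convention.  Used as the coordinate substrate for CLIP tags, peaks and
#' binding sites.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end exclusive end; must satisfy `end > start`.
#' @param strand `"+"` or `"-"`.
#' @return a list of class `"ginterval"`.
#' @export
ginterval <- function(chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop_("invalid interval [%s, %s): need 0 <= start < end", start, end)
  if (!strand %in% c("+", "-")) stop_("strand must be '+' or '-', got '%s'", strand)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand), class = "ginterval")
}

#' Stranded gene model with derived region structure
#'
#' Builds a gene model from exon intervals and an optional genomic CDS span,
#' deriving introns, 5'/3' UTRs and a downstream extension (default 10 kb past
#' the annotated 3' end, to capture non-annotated 3'UTR variants).  For coding
#' genes the 5'UTR, CDS and 3'UTR exactly partition the exonic span.  Genes
#' without a CDS get a single whole-exon `noncoding` region.
#'
#' @param gene_id gene identifier.
#' @param chrom,strand chromosome and strand of the gene.
#' @param exons two-column integer matrix (`start`, `end`), 0-based half-open;
#'   must be non-overlapping.
#' @param cds_span length-2 vector `c(thick_start, thick_end)` in genomic
#'   coordinates, or `NULL` for a noncoding gene.  `thick_start == thick_end`
#'   also means noncoding (BED12 convention).
#' @param downstream length (nt) of the downstream extension past the
#'   annotated 3' end.
#' @return a list of class `"gene_model"` with elements `exons`, `cds`,
#'   `utr5`, `utr3`, `introns`, `noncoding`, `downstream_ext`, `tx_start`,
#'   `tx_end`, `span` (the extended span used as peak-calling background).
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_span = NULL,
                       downstream = 10000L) {
  if (!strand %in% c("+", "-")) stop_("gene %s: strand must be '+' or '-'", gene_id)
  exons <- .mat(exons[, 1L], exons[, 2L])
  if (any(exons[, 2L] <= exons[, 1L]))
    stop_("gene %s: exon with non-positive length", gene_id)
  n <- nrow(exons)
  if (n > 1L && any(exons[-1L, 1L] < exons[-n, 2L]))
    stop_("gene %s: overlapping exons within one transcript", gene_id)
  tx_start <- unname(exons[1L, 1L]); tx_end <- unname(exons[n, 2L])

  introns <- if (n > 1L) .mat(exons[-n, 2L], exons[-1L, 1L]) else .mat(integer(0), integer(0))

  empty <- .mat(integer(0), integer(0))
  coding <- !is.null(cds_span) && cds_span[2L] > cds_span[1L]
  if (coding) {
    ts <- as.integer(cds_span[1L]); te <- as.integer(cds_span[2L])
    s <- exons[, 1L]; e <- exons[, 2L]
    clip <- function(lo, hi) {
      cs <- pmax(s, lo); ce <- pmin(e, hi)
      keep <- ce > cs
      .mat(cs[keep], ce[keep])
    }
    cds   <- clip(ts, te)
    left  <- clip(tx_start, ts)
    right <- clip(te, tx_end)
    if (strand == "+") { utr5 <- left;  utr3 <- right }
    else               { utr5 <- right; utr3 <- left  }
    noncoding <- empty
  } else {
    cds <- utr5 <- utr3 <- empty
    noncoding <- exons
  }

  downstream <- as.integer(downstream)
  ext <- if (strand == "+") c(tx_end, tx_end + downstream)
         else c(max(0L, tx_start - downstream), tx_start)
  span <- c(min(tx_start, ext[1L]), max(tx_end, ext[2L]))

  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, exons = exons, cds = cds, utr5 = utr5,
                 utr3 = utr3, introns = introns, noncoding = noncoding,
                 downstream_ext = as.integer(ext), tx_start = tx_start,
                 tx_end = tx_end, span = as.integer(span), coding = coding),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  w <- function(m) sum(m[, 2L] - m[, 1L])
  cat(sprintf("gene_model %s  %s:%d-%d (%s)  %d exon(s)\n", x$gene_id, x$chrom,
              x$tx_start, x$tx_end, x$strand, nrow(x$exons)))
  cat(sprintf("  utr5 %d nt | cds %d nt | utr3 %d nt | introns %d nt | +%d nt downstream\n",
              w(x$utr5), w(x$cds), w(x$utr3), w(x$introns),
              x$downstream_ext[2L] - x$downstream_ext[1L]))
  invisible(x)
}

## region labels in exclusive-mode precedence order
.REGION_PRECEDENCE <- c("UTR3", "CDS", "UTR5", "noncoding", "intron", "downstream")

.region_matrix <- function(gm, label) {
  switch(label,
         UTR3 = gm$utr3, CDS = gm$cds, UTR5 = gm$utr5,
         noncoding = gm$noncoding, intron = gm$introns,
         downstream = matrix(gm$downstream_ext, nrow = 1L,
                             dimnames = list(NULL, c("start", "end"))))
}

#' Assign transcript-region labels to an interval
#'
#' Labels an interval by the gene regions it overlaps.  In `non_exclusive`
#' mode every overlapped region is returned (so a site spanning a CDS
#' exon/intron boundary is both `CDS` and `intron`); in `exclusive` mode only
#' the highest-precedence label under `UTR3 > CDS > UTR5 > intron >
#' downstream` is returned.  Intervals overlapping nothing return `"none"`.
#'
#' @param iv a [ginterval()] (or any list with `chrom`, `start`, `end`,
#'   `strand`) on the same chromosome and strand as `gm`.
#' @param gm a [gene_model()].
#' @param mode `"non_exclusive"` (default) or `"exclusive"`.
#' @return character vector of region labels (length 1 in exclusive mode).
#' @export
assign_region <- function(iv, gm, mode = c("non_exclusive", "exclusive")) {
  mode <- match.arg(mode)
  if (iv$end <= iv$start) stop_("zero-length interval")
  if (!identical(iv$chrom, gm$chrom) || !identical(iv$strand, gm$strand))
    stop_("interval %s:%d-%d(%s) not on gene %s chrom/strand",
          iv$chrom, iv$start, iv$end, iv$strand, gm$gene_id)
  hit <- vapply(.REGION_PRECEDENCE, function(lbl)
    .ov_any(iv$start, iv$end, .region_matrix(gm, lbl)), logical(1L))
  labels <- .REGION_PRECEDENCE[hit]
  if (length(labels) == 0L) return("none")
  if (mode == "exclusive") labels[1L] else labels
}

#' Signed distance from an interval midpoint to the transcript 3' end
#'
#' Offset, in transcript orientation, of the interval midpoint from the
#' annotated 3'-terminal base (negative = upstream of the 3' end).  For
#' even-length intervals the midpoint rounds toward the 5' side.
#'
#' @inheritParams assign_region
#' @return a signed integer offset in nucleotides.
#' @export
distance_to_transcript_end <- function(iv, gm) {
  if (iv$end <= iv$start) stop_("zero-length interval")
  if (!identical(iv$chrom, gm$chrom) || !identical(iv$strand, gm$strand))
    stop_("interval not on gene %s chrom/strand", gm$gene_id)
  len <- iv$end - iv$start
  if (gm$strand == "+") {
    mid <- iv$start + (len - 1L) %/% 2L       # even length: lower (5') base
    mid - (gm$tx_end - 1L)
  } else {
    mid <- iv$start + len %/% 2L              # even length: higher (5') base
    gm$tx_start - mid
  }
}

## ---- annotation file readers -------------------------------------------

#' Load gene models from BED12 or GTF
#'
#' Reads an annotation file and derives one [gene_model()] per gene.  BED12 is
#' taken natively (0-based; `thickStart`/`thickEnd` give the CDS span; one
#' line per gene).  GTF is converted on read; when a gene has several
#' transcript isoforms the union gene model is used: union of all exons, CDS
#' span from the longest-CDS transcript.
#'
#' @param path annotation file.
#' @param format `"bed12"` or `"gtf"`.
#' @param downstream downstream-extension length in nt (default 10,000).
#' @return a named list of [gene_model()] objects.
#' @export
load_gene_models <- function(path, format = c("bed12", "gtf"), downstream = 10000L) {
  format <- match.arg(format)
  if (format == "bed12") .load_bed12(path, downstream) else .load_gtf(path, downstream)
}

.load_bed12 <- function(path, downstream) {
  ## quick structural validation so malformed records are reported by line
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 12L))
    stop_("%s: line %d has %d fields, expected 12 (BED12)",
          path, which(nf != 12L)[1L], nf[nf != 12L][1L])
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- rtracklayer::blocks(gr)   # absolute, 1-based exon ranges
  thick <- gr$thick
  models <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    b <- blocks[[i]]
    exons <- cbind(IRanges::start(b) - 1L, IRanges::end(b))
    ts <- IRanges::start(thick)[i] - 1L
    te <- IRanges::end(thick)[i]
    cds_span <- if (te > ts) c(ts, te) else NULL
    models[[i]] <- gene_model(gr$name[i], as.character(GenomicRanges::seqnames(gr)[i]),
                              as.character(BiocGenerics::strand(gr)[i]),
                              exons, cds_span, downstream)
  }
  names(models) <- vapply(models, `[[`, character(1L), "gene_id")
  models
}

.load_gtf <- function(path, downstream) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop_("%s: no exon features found", path)
  gid <- ex$gene_id
  models <- list()
  cds_all <- gr[gr$type == "CDS"]
  for (g in unique(gid)) {
    e <- ex[gid == g]
    red <- GenomicRanges::reduce(e)     # union exon model across isoforms
    exons <- cbind(GenomicRanges::start(red) - 1L, GenomicRanges::end(red))
    cds_g <- cds_all[cds_all$gene_id == g]
    cds_span <- NULL
    if (length(cds_g) > 0L) {
      tx <- cds_g$transcript_id %||% rep("tx1", length(cds_g))
      tot <- tapply(GenomicRanges::width(cds_g), tx, sum)
      best <- names(tot)[which.max(tot)]   # longest coding transcript
      cg <- cds_g[tx == best]
      cds_span <- c(min(GenomicRanges::start(cg)) - 1L, max(GenomicRanges::end(cg)))
    }
    models[[g]] <- gene_model(g, as.character(GenomicRanges::seqnames(e)[1L]),
                              as.character(BiocGenerics::strand(e)[1L]),
                              exons, cds_span, downstream)
  }
  models
}

#' Write a derived region track as BED6
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @param region one of `"utr3"`, `"cds"`, `"utr5"`, `"introns"`,
#'   `"noncoding"`, `"exons"`.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(models, path,
                              region = c("utr3", "cds", "utr5", "introns",
                                         "noncoding", "exons")) {
  region <- match.arg(region)
  rows <- lapply(models, function(gm) {
    m <- gm[[region]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(chrom = gm$chrom, start = m[, 1L], end = m[, 2L],
               name = gm$gene_id, score = 0L, strand = gm$strand)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
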