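#' Classify genes by binding region and magnitude
#'
#' A gene belongs to class `C` (UTR3, CDS, intron) iff it has at least one
#' robust site overlapping region `C`.  In `non_exclusive` mode (the
#' default) a gene can belong to several classes; in `exclusive` mode each
#' site contributes only its highest-precedence region label.  Genes with no
#' robust site in any transcript region form the background.  When sites
#' carry a `tier` column the per-class top-tier membership (e.g. a gene with
#' a top-20%-PH UTR3 site) is recorded too.
#'
#' @param sites robust-site table annotated by [annotate_sites()] (and
#'   optionally tiered by [stratify_by_ph()]).
#' @param models named list of [gene_model()] objects (the gene universe).
#' @param mode `"non_exclusive"` or `"exclusive"`.
#' @return data.frame with one row per gene in `models`: `gene_id`,
#'   `classes` (list-column, possibly empty), `is_target`, and logical
#'   columns `UTR3`, `CDS`, `intron`, `UTR3_top`, `CDS_top`.
#' @export
classify_targets <- function(sites, models, mode = c("non_exclusive", "exclusive")) {
  mode <- match.arg(mode)
  genes <- names(models)
  unknown <- setdiff(unique(sites$gene_id), genes)
  if (length(unknown))
    stop_("site references unknown gene '%s'", unknown[1L])
  cls <- c("UTR3", "CDS", "intron")
  memb <- matrix(FALSE, length(genes), length(cls), dimnames = list(genes, cls))
  top <- matrix(FALSE, length(genes), 2L, dimnames = list(genes, c("UTR3", "CDS")))
  has_site <- stats::setNames(rep(FALSE, length(genes)), genes)
  tier <- sites$tier %||% rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    g <- sites$gene_id[i]
    has_site[g] <- TRUE
    regs <- if (mode == "non_exclusive") sites$regions[[i]] else sites$region[i]
    for (r in intersect(regs, cls)) {
      memb[g, r] <- TRUE
      if (r %in% colnames(top) && isTRUE(tier[i] == "top")) top[g, r] <- TRUE
    }
  }
  if (mode == "exclusive") {
    ## one class per gene, highest precedence among UTR3 > CDS > intron
    for (g in genes[rowSums(memb[, , drop = FALSE]) > 0L]) {
      keep <- cls[which(memb[g, ])[1L]]
      memb[g, setdiff(cls, keep)] <- FALSE
      top[g, setdiff(colnames(top), keep)] <- FALSE
    }
  }
  data.frame(gene_id = genes,
             classes = I(lapply(genes, function(g) cls[memb[g, ]])),
             is_target = unname(has_site),
             UTR3 = unname(memb[, "UTR3"]), CDS = unname(memb[, "CDS"]),
             intron = unname(memb[, "intron"]),
             UTR3_top = unname(top[, "UTR3"]), CDS_top = unname(top[, "CDS"]),
             row.names = NULL)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_x - ECDF_y|`, with the p-value from exact enumeration when
#' `n_x * n_y <= 10^4` and the asymptotic Kolmogorov distribution otherwise
#' (via [stats::ks.test()], two-sided).
#'
#' @param x,y numeric samples (both non-empty).
#' @return list: `D`, `p_value`, `n_x`, `n_y`, `median_shift`
#'   (`median(x) - median(y)`).
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop_("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided",
                                        exact = length(x) * length(y) <= 1e4))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n_x = length(x), n_y = length(y),
       median_shift = stats::median(x) - stats::median(y))
}

## ECDF table of a sample over a shared grid, for CDF plotting
.cdf_table <- function(values, grid) {
  if (length(values) == 0L)
    return(data.frame(log2fc = grid, ecdf = NA_real_))
  data.frame(log2fc = grid, ecdf = stats::ecdf(values)(grid))
}

#' Distribution-shift tests of target classes against non-target background
#'
#' For each requested target class (and top-PH-tier subclass) the log2
#' fold-change distribution is compared with that of genes carrying no
#' robust site, by a two-sided two-sample KS test.  Benjamini-Hochberg
#' q-values across the family of class tests are reported alongside the raw
#' p-values.  Classes with fewer than 10 genes are flagged low-power, never
#' suppressed.
#'
#' @param assignments output of [classify_targets()].
#' @param records output of [expression_records()]; only genes with
#'   `pass == TRUE` are analysed.
#' @param value which fold change to test: `"log2fc_rna"` (abundance,
#'   default), `"log2fc_rp"`, or `"dte"`.
#' @param classes which class columns of `assignments` to test.
#' @return data.frame: `class`, `n_class`, `n_background`, `D`, `p_value`,
#'   `q_value`, `median_shift`, `low_power`; the per-class ECDF tables are
#'   attached as attribute `"cdf_tables"` (shared grid, background included).
#' @export
run_shift_analysis <- function(assignments, records, value = "log2fc_rna",
                               classes = c("UTR3", "CDS", "intron",
                                           "UTR3_top", "CDS_top")) {
  recs <- records[records$pass, , drop = FALSE]
  idx <- match(recs$gene_id, assignments$gene_id)
  if (anyNA(idx)) stop_("expression records contain genes absent from assignments")
  asg <- assignments[idx, , drop = FALSE]
  vals <- recs[[value]]
  bg <- vals[!asg$is_target]
  if (length(bg) == 0L) stop_("no background (site-free) genes pass the filters")
  res <- lapply(classes, function(cl) {
    sel <- asg[[cl]]
    if (is.null(sel)) stop_("unknown class column '%s'", cl)
    x <- vals[sel]
    if (length(x) == 0L)
      return(data.frame(class = cl, n_class = 0L, n_background = length(bg),
                        D = NA_real_, p_value = NA_real_,
                        median_shift = NA_real_, low_power = TRUE))
    ks <- ks_two_sample(x, bg)
    data.frame(class = cl, n_class = ks$n_x, n_background = ks$n_y,
               D = ks$D, p_value = ks$p_value, median_shift = ks$median_shift,
               low_power = ks$n_x < 10L)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out <- out[, c("class", "n_class", "n_background", "D", "p_value", "q_value",
                 "median_shift", "low_power")]
  grid <- sort(unique(vals))
  tabs <- c(list(background = .cdf_table(bg, grid)),
            stats::setNames(lapply(classes, function(cl)
              .cdf_table(vals[asg[[cl]]], grid)), classes))
  attr(out, "cdf_tables") <- tabs
  out
}

#' Restrict robust sites to those overlapping a CITS position
#'
#' Optional stringent mode for target classification: keeps only sites that
#' contain at least one statistically robust cross-link-induced truncation
#' site.
#'
#' @param sites robust-site table.
#' @param cits CITS table from [call_cits()].
#' @return the subset of `sites` overlapping a CITS position.
#' @export
restrict_to_cits <- function(sites, cits) {
  if (nrow(sites) == 0L || nrow(cits) == 0L) return(sites[integer(0), , drop = FALSE])
  keep <- vapply(seq_len(nrow(sites)), function(i) {
    any(cits$chrom == sites$chrom[i] & cits$strand == sites$strand[i] &
          cits$position >= sites$start[i] & cits$position < sites$end[i])
  }, logical(1L))
  sites[keep, , drop = FALSE]
}
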