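## small site/model scaffold: gene gA with a UTR3 and a CDS site, gB with an
## intronic site, gC site-free
fix_classification <- function(mode = "non_exclusive") {
  models <- list(gA = fix_gene_plus(), gB = fix_gene_plus(), gC = fix_gene_plus())
  models$gB$gene_id <- "gB"; models$gC$gene_id <- "gC"
  sites <- rbind(fix_peak(gene = "gA", start = 410L, end = 440L, ph = 8L),
                 fix_peak(gene = "gA", start = 160L, end = 190L, ph = 7L),
                 fix_peak(gene = "gB", start = 210L, end = 240L, ph = 9L))
  sites$site_id <- sprintf("%s:%d", sites$gene_id, sites$start)
  sites <- annotate_sites(sites, models)
  classify_targets(sites, models, mode)
}

test_that("target classification is region-aware and mode-sensitive", {
  asg <- fix_classification("non_exclusive")
  gA <- asg[asg$gene_id == "gA", ]
  expect_setequal(gA$classes[[1]], c("UTR3", "CDS"))
  expect_true(gA$UTR3 && gA$CDS)
  gB <- asg[asg$gene_id == "gB", ]
  expect_equal(gB$classes[[1]], "intron")
  expect_false(asg[asg$gene_id == "gC", "is_target"])
  ## exclusive mode keeps only the highest-precedence class per gene
  asg_ex <- fix_classification("exclusive")
  gA_ex <- asg_ex[asg_ex$gene_id == "gA", ]
  expect_equal(gA_ex$classes[[1]], "UTR3")
  expect_false(gA_ex$CDS)
  ## non-exclusive membership is a superset of exclusive, gene by gene
  for (cl in c("UTR3", "CDS", "intron"))
    expect_true(all(asg_ex[[cl]] <= asg[[cl]]))
  ## unknown gene rejected
  bad <- fix_peak(gene = "nope")
  bad$site_id <- "x"; bad$region <- "UTR3"; bad$regions <- list("UTR3")
  expect_error(classify_targets(bad, list(gA = fix_gene_plus())), "unknown gene")
})

test_that("KS statistic matches the brute-force sup oracle", {
  ## worked example: D attained at t = 2
  r <- ks_two_sample(c(0, 1, 2), c(0.5, 1.5, 2.5, 3.5))
  expect_equal(r$D, 0.5)
  ## identical multisets
  r0 <- ks_two_sample(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(r0$D, 0)
  expect_equal(r0$p_value, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
  set.seed(31)
  for (i in 1:100) {
    x <- round(rnorm(sample(2:40, 1)), 2)
    y <- round(rnorm(sample(2:40, 1), mean = runif(1, -1, 1)), 2)
    expect_equal(ks_two_sample(x, y)$D, oracle_ks_D(x, y), tolerance = 1e-12)
  }
})

test_that("KS D is invariant under common strictly monotone transforms", {
  set.seed(32)
  x <- rnorm(30); y <- rnorm(40, 0.3)
  d0 <- ks_two_sample(x, y)$D
  for (f in list(function(v) v^3, exp, function(v) atan(v) * 2)) {
    expect_equal(ks_two_sample(f(x), f(y))$D, d0)
  }
})

test_that("shift analysis reports per-class KS against the no-site background", {
  set.seed(33)
  n <- 260
  genes <- sprintf("g%03d", 1:n)
  is_target <- rep(c(TRUE, FALSE), c(60, 200))
  asg <- data.frame(gene_id = genes, is_target = is_target,
                    UTR3 = is_target, CDS = FALSE, intron = FALSE,
                    UTR3_top = FALSE, CDS_top = FALSE)
  recs <- data.frame(gene_id = genes, pass = TRUE,
                     log2fc_rna = rnorm(n, ifelse(is_target, 0.5, 0), 0.3))
  res <- run_shift_analysis(asg, recs, "log2fc_rna", classes = c("UTR3", "CDS"))
  utr3 <- res[res$class == "UTR3", ]
  expect_lt(utr3$p_value, 1e-6)
  expect_gt(utr3$median_shift, 0.3)
  expect_equal(utr3$n_class, 60)
  expect_equal(utr3$n_background, 200)
  ## empty class flagged, not dropped
  cds <- res[res$class == "CDS", ]
  expect_true(cds$low_power)
  expect_true(is.na(cds$D))
  ## CDF tables cover background and classes on a shared grid
  tabs <- attr(res, "cdf_tables")
  expect_setequal(names(tabs), c("background", "UTR3", "CDS"))
  expect_equal(max(tabs$background$ecdf), 1)
})

test_that("label-permutation p-values are calibrated", {
  set.seed(34)
  vals <- rnorm(150)
  hits <- 0L
  for (i in 1:100) {
    sel <- sample(150, 40)
    p <- ks_two_sample(vals[sel], vals[-sel])$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  ## under the null the rejection count is Binomial(100, ~0.05)
  expect_lte(hits, qbinom(0.999, 100, 0.05))
})

test_that("CITS-stringent mode restricts sites to truncation support", {
  sites <- rbind(fix_peak(gene = "gA", start = 100L, end = 150L),
                 fix_peak(gene = "gB", start = 300L, end = 350L))
  cits <- data.frame(chrom = "chr1", position = 120L, strand = "+",
                     gene_id = "gA", peak_id = "gA:100-150",
                     truncation_count = 9L, n_truncations = 10L,
                     p_value = 1e-10, q_value = 1e-8)
  kept <- restrict_to_cits(sites, cits)
  expect_equal(kept$gene_id, "gA")
  expect_equal(nrow(restrict_to_cits(sites, cits[0, ])), 0)
})
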