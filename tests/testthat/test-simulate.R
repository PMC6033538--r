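## small, fast configuration shared by these tests
small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 60L,
             classes = c(UTR3 = 10L, CDS = 6L, intron = 4L),
             depth = 1e5, cov_depth = 1e5, ...)
}

test_that("identical configurations give byte-identical fixtures", {
  d1 <- file.path(tempdir(), "bundle_a"); d2 <- file.path(tempdir(), "bundle_b")
  p1 <- write_fixture(simulate_dataset(small_cfg()), d1)
  p2 <- write_fixture(simulate_dataset(small_cfg()), d2)
  expect_equal(names(p1), names(p2))
  for (nm in names(p1))
    expect_equal(unname(tools::md5sum(p1[nm])), unname(tools::md5sum(p2[nm])),
                 label = nm)
  ## a different seed changes the data
  p3 <- write_fixture(simulate_dataset(small_cfg(seed = 2L)),
                      file.path(tempdir(), "bundle_c"))
  expect_false(tools::md5sum(p1[["truth.tsv"]]) == tools::md5sum(p3[["truth.tsv"]]))
  unlink(c(d1, d2, file.path(tempdir(), "bundle_c")), recursive = TRUE)
})

test_that("fixtures round-trip losslessly through the package readers", {
  b <- simulate_dataset(small_cfg())
  out <- file.path(tempdir(), "bundle_rt")
  paths <- write_fixture(b, out)
  ## tags: identical multiset of intervals with provenance
  tag_files <- paths[grep("^tags_", names(paths))]
  back <- read_clip_tags(tag_files)
  key <- function(t) sort(paste(t$chrom, t$start, t$end, t$strand,
                                t$replicate, t$antiserum))
  expect_equal(key(back), key(b$tags))
  ## gene models: exon/CDS structure reconstructed exactly
  models <- load_gene_models(paths[["genes.bed"]], "bed12",
                             downstream = b$cfg$downstream)
  expect_equal(names(models), names(b$models))
  for (g in names(models)[c(1, 2, 30, 60)]) {
    expect_equal(models[[g]]$exons, b$models[[g]]$exons, ignore_attr = TRUE)
    expect_equal(models[[g]]$cds, b$models[[g]]$cds, ignore_attr = TRUE)
    expect_equal(models[[g]]$utr3, b$models[[g]]$utr3, ignore_attr = TRUE)
  }
  ## counts round-trip
  rna <- read_count_matrix(paths[["rna_counts.tsv"]], paths[["rna_meta.tsv"]],
                           paths[["lengths.tsv"]])
  expect_equal(rna$counts, b$rna$counts)
  expect_equal(rna$meta$genotype, b$rna$meta$genotype)
  ## truth table conservation and BED6 validity
  truth <- utils::read.delim(paths[["truth.tsv"]])
  expect_equal(nrow(truth), b$cfg$n_genes)
  bed <- utils::read.delim(tag_files[[1]], header = FALSE)
  expect_true(all(bed$V2 < bed$V3))
  expect_true(all(bed$V6 %in% c("+", "-")))
  unlink(out, recursive = TRUE)
})

test_that("simulated counts have negative-binomial moments", {
  ## many replicates of one configuration give per-gene moment estimates;
  ## NB law: mean mu, variance mu + phi mu^2
  cfg <- sim_config(seed = 77, n_genes = 20L,
                    classes = c(UTR3 = 0L, CDS = 0L, intron = 0L),
                    n_reps_expr = 2500L, depth = 2000, dispersion = 0.1,
                    cov_depth = 1e4)
  b <- simulate_dataset(cfg)
  wt <- b$rna$counts[, b$rna$meta$genotype == "WT"]   # 20 x 2500 null draws
  mu_hat <- rowMeans(wt)
  var_hat <- apply(wt, 1, stats::var)
  big <- mu_hat > 50                                  # stable moment genes
  expect_gt(sum(big), 2)
  expect_true(all(abs(mu_hat[big] - b$truth$rel_abund[big] /
                        sum(b$truth$rel_abund) * 2000) < 3))
  expected_var <- mu_hat[big] + 0.1 * mu_hat[big]^2
  expect_true(all(abs(var_hat[big] / expected_var - 1) < 0.15))
})

test_that("tags are strand-consistent and concentrated at planted sites", {
  b <- simulate_dataset(small_cfg())
  strands <- vapply(b$models, `[[`, character(1L), "strand")
  expect_equal(unname(strands[b$tags$gene_id]), b$tags$strand)
  ## site tags overlap the planted center for target genes
  tr <- b$truth[b$truth$class == "UTR3", ][1, ]
  tg <- b$tags[b$tags$gene_id == tr$gene_id, ]
  covering <- sum(tg$start <= tr$site_center & tg$end > tr$site_center)
  expect_gt(covering, 10)
  ## truncations of exact-mode tags pile at one position
  expect_gt(max(table(tg$truncation)), 5)
})

test_that("default effect structure matches the documented target plan", {
  cfg <- sim_config()
  ## CDS translation effect exceeds the UTR3 effect, both positive
  expect_gt(abs(cfg$delta_te$CDS[["bulk"]]), abs(cfg$delta_te$UTR3[["bulk"]]))
  expect_gt(abs(cfg$delta_te$UTR3[["bulk"]]), 0)
  ## top-tier UTR3 sites: no abundance effect but a real TE effect
  expect_equal(cfg$delta_abund$UTR3[["top"]], 0)
  expect_gt(cfg$delta_te$UTR3[["top"]], 0)
  ## infeasible plans rejected
  expect_error(sim_config(n_genes = 10L,
                          classes = c(UTR3 = 20L, CDS = 0L, intron = 0L)),
               "more target genes")
})

test_that("coverage profiles share shape across genotypes", {
  b <- simulate_dataset(small_cfg())
  tr <- b$coverage$transcripts[[b$truth$gene_id[b$truth$class == "CDS"][1]]]
  expect_equal(length(tr$shape), tr$length)
  expect_equal(sum(tr$shape), 1, tolerance = 1e-9)
  ## per-genotype read centers live on the transcript
  expect_true(all(tr$wt_centers >= 0 & tr$wt_centers < tr$length))
  expect_true(all(tr$ko_centers >= 0 & tr$ko_centers < tr$length))
})
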