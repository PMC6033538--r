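test_that("pileup matches hand-computed depths and conserves tag length", {
  gm <- gene_model("g", "chr1", "+", rbind(c(0L, 100L)), NULL, 0L)
  tg <- clip_tags(data.frame(chrom = "chr1", start = c(10L, 15L, 18L),
                             end = c(20L, 25L, 22L), strand = "+",
                             replicate = "r1", antiserum = "A"))
  d <- pileup(tg, gm)
  expect_equal(d[19], 3)          # base 18 covered by all three tags
  expect_equal(max(d), 3)
  expect_equal(sum(d), sum(tg$end - tg$start))
  ## no tags -> all-zero vector
  d0 <- pileup(tg[0, ], gm)
  expect_true(all(d0 == 0))
  expect_length(d0, 100)
  ## conservation on random instances (tags clipped to the span)
  set.seed(3)
  for (i in 1:25) {
    st <- sample(-20:110, sample(1:30, 1L), replace = TRUE)
    len <- sample(5:40, length(st), replace = TRUE)
    tg <- clip_tags(data.frame(chrom = "chr1", start = st, end = st + len,
                               strand = "+", replicate = "r1", antiserum = "A"))
    tg <- tg[tg$start >= -100, ]
    d <- suppressWarnings(pileup(tg, gm))
    clipped <- pmin(tg$end, 100L) - pmax(tg$start, 0L)
    expect_equal(sum(d), sum(pmax(clipped, 0L)))
  }
})

test_that("candidate peaks split at deep valleys and merge over shallow ones", {
  gm <- gene_model("g", "chr1", "+", rbind(c(0L, 200L)), NULL, 0L)
  stack <- function(s, e, n) data.frame(chrom = "chr1", start = rep(s, n),
                                        end = rep(e, n), strand = "+",
                                        replicate = "r1", antiserum = "A")
  ## two 10-deep stacks bridged by 2 tags: valley depth 2 < 50% of 12 -> split
  tg <- clip_tags(rbind(stack(0, 30, 10), stack(40, 70, 10), stack(25, 45, 2)))
  pk <- call_peaks(tg, gm, alpha = 1, n_perm = 20)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$ph, c(12, 12))
  ## bridged by 10 tags: valley depth 10 = 50% of the flanking maxima (20)
  ## -> no split, one peak
  tg2 <- clip_tags(rbind(stack(0, 30, 10), stack(40, 70, 10), stack(25, 45, 10)))
  pk2 <- call_peaks(tg2, gm, alpha = 1, n_perm = 20)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$ph, 20)
})

test_that("permutation FDR calls a stacked site and spares sparse genes", {
  gm <- gene_model("g", "chr1", "+", rbind(c(0L, 2000L)), NULL, 8000L)
  set.seed(42)
  site <- 500L + sample(-10:10, 50, replace = TRUE)
  bg <- sort(sample(0:9960, 10))
  tg <- clip_tags(data.frame(chrom = "chr1", start = c(site, bg),
                             end = c(site, bg) + 35L, strand = "+",
                             replicate = "r1", antiserum = "A"))
  pk <- call_peaks(tg, gm, alpha = 0.01, n_perm = 100)
  expect_equal(nrow(pk), 1)
  expect_lt(pk$fdr, 0.01)
  expect_true(pk$start <= 500 && pk$end > 500)
  expect_true(all(pk$ph <= pk$n_tags))
  ## a single tag can never pass at default stringency
  one <- tg[1, , drop = FALSE]
  expect_equal(nrow(call_peaks(one, gm, alpha = 0.01, n_perm = 50)), 0)
  ## unstable permutation count rejected
  expect_error(call_peaks(tg, gm, n_perm = 10), "n_perm")
})

test_that("robust-site thresholds are strict and support-aware", {
  ## PH 6, replicates {r1,r2,r3}, antisera {A,B} -> retained
  ok <- define_robust_sites(fix_peak(ph = 6L, reps = c("r1", "r2", "r3"),
                                     sera = c("A", "A", "B")))
  expect_equal(nrow(ok), 1)
  ## PH exactly 5 -> rejected (threshold is strict)
  expect_equal(nrow(define_robust_sites(fix_peak(ph = 5L))), 0)
  ## single antiserum -> rejected
  expect_equal(nrow(define_robust_sites(
    fix_peak(ph = 8L, reps = c("r1", "r2", "r3"), sera = "A"))), 0)
  ## overlapping peaks merge to the union interval with max PH
  p <- rbind(fix_peak(start = 0L, end = 50L, ph = 6L, reps = "r1", sera = "A"),
             fix_peak(start = 40L, end = 90L, ph = 9L, reps = "r2", sera = "A"),
             fix_peak(start = 80L, end = 120L, ph = 7L, reps = "r3", sera = "B"))
  m <- define_robust_sites(p)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0L, 120L))
  expect_equal(m$ph, 9L)
  expect_equal(m$n_replicates, 3L)
  ## pooled preset: needs support from >5 replicates
  pool5 <- fix_peak(ph = 9L, reps = paste0("r", 1:5), sera = c("A", "B"))
  pool6 <- fix_peak(ph = 9L, reps = paste0("r", 1:6), sera = c("A", "B"))
  expect_equal(nrow(define_robust_sites(pool5, mode = "pooled")), 0)
  expect_equal(nrow(define_robust_sites(pool6, mode = "pooled")), 1)
})

test_that("raising support thresholds never increases the site count", {
  set.seed(5)
  for (trial in 1:10) {
    peaks <- do.call(rbind, lapply(1:20, function(i)
      fix_peak(gene = sample(c("g1", "g2"), 1L),
               start = sample(0:500, 1L), end = 600L,
               ph = sample(1:12, 1L),
               reps = sample(paste0("r", 1:6), sample(1:5, 1L)),
               sera = sample(c("A", "B"), sample(1:2, 1L)))))
    peaks$end <- peaks$start + sample(10:60, nrow(peaks), replace = TRUE)
    n <- vapply(1:8, function(mp)
      nrow(define_robust_sites(peaks, min_ph = mp, min_replicates = 2L,
                               min_antisera = 1L)), numeric(1))
    expect_true(all(diff(n) <= 0))
    n2 <- vapply(1:5, function(mr)
      nrow(define_robust_sites(peaks, min_ph = 2L, min_replicates = mr,
                               min_antisera = 1L)), numeric(1))
    expect_true(all(diff(n2) <= 0))
  }
})

test_that("PH stratification ranks deterministically with documented ties", {
  sites <- do.call(rbind, lapply(1:10, function(i)
    fix_peak(gene = sprintf("g%02d", i), start = i * 100L, end = i * 100L + 30L,
             ph = i)))
  sites$site_id <- sprintf("%s:%d-%d", sites$gene_id, sites$start, sites$end)
  s <- stratify_by_ph(sites, 0.20, "global")
  expect_setequal(s$site_id[s$tier == "top"], sites$site_id[sites$ph >= 9])
  ## top_fraction 1 -> everything top
  expect_true(all(stratify_by_ph(sites, 1.0, "global")$tier == "top"))
  ## all-equal PH: tie-break on site_id is reproducible
  sites$ph <- 5L; sites$n_tags <- 5L
  s1 <- stratify_by_ph(sites, 0.2, "global")
  s2 <- stratify_by_ph(sites, 0.2, "global")
  expect_identical(s1$tier, s2$tier)
  expect_setequal(s1$site_id[s1$tier == "top"], sort(sites$site_id)[1:2])
})

test_that("CITS detection follows the binomial truncation model", {
  peak <- fix_peak(start = 100L, end = 120L, ph = 10L)
  mk <- function(trunc) clip_tags(data.frame(
    chrom = "chr1", start = trunc, end = trunc + 35L, strand = "+",
    replicate = "r1", antiserum = "A"))
  ## 9 of 10 truncations at one position in a width-20 peak
  tg <- mk(c(rep(105L, 9L), 112L))
  cits <- call_cits(tg, peak, alpha = 0.05)
  expect_equal(cits$position, 105L)
  expect_equal(cits$truncation_count, 9L)
  ## p matches the exact binomial upper tail (~9.8e-11)
  expect_equal(cits$p_value, sum(dbinom(9:10, 10, 0.05)), tolerance = 1e-12)
  ## uniform truncations: one per position, nothing significant
  expect_equal(nrow(call_cits(mk(100:119), peak)), 0)
  ## no truncations in the peak -> empty
  expect_equal(nrow(call_cits(mk(500L), peak)), 0)
})

test_that("planted AU-rich motif dominates the k-mer ranking", {
  set.seed(9)
  mk_win <- function(plant) {
    s <- sample(c("A", "C", "G", "U"), 30, replace = TRUE)
    if (plant) s[12:19] <- strsplit("UAUUUAUU", "")[[1]]
    paste(s, collapse = "")
  }
  wins <- vapply(1:40, function(i) mk_win(TRUE), character(1))
  tab <- kmer_enrichment(wins, k = 8, n_shuffle = 100, seed = 2)
  expect_equal(tab$kmer[1], "UAUUUAUU")
  expect_gt(tab$z[1], 5)
  ## shuffled-background windows show no strong outlier
  null_wins <- vapply(1:40, function(i) mk_win(FALSE), character(1))
  tab0 <- kmer_enrichment(null_wins, k = 8, n_shuffle = 100, seed = 3)
  expect_lt(max(abs(tab0$z)), 4.5)
  ## single window still yields finite z (sd from shuffles)
  tab1 <- kmer_enrichment(wins[1], k = 8, n_shuffle = 50, seed = 4)
  expect_true(all(is.finite(tab1$z)))
  ## short windows excluded with a warning
  expect_warning(kmer_enrichment(c(wins[1], "ACGU"), k = 8, n_shuffle = 10,
                                 seed = 5), "shorter")
})

test_that("dinucleotide shuffle preserves dinucleotide composition", {
  set.seed(21)
  dinucs <- function(ch) paste0(ch[-length(ch)], ch[-1])
  for (i in 1:20) {
    ch <- sample(c("A", "C", "G", "U"), 40, replace = TRUE)
    sh <- clipshift:::.dinuc_shuffle(ch)
    expect_equal(sort(dinucs(sh)), sort(dinucs(ch)))
    expect_equal(sh[1], ch[1])
    expect_equal(sh[length(sh)], ch[length(ch)])
  }
})
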