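test_that("BED12 loading partitions a two-exon coding gene correctly", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t500\tgA\t0\t+\t150\t400\t0\t2\t100,200\t0,200", bed)
  gm <- load_gene_models(bed, "bed12", downstream = 1000L)[["gA"]]
  w <- function(m) sum(m[, 2] - m[, 1])
  ## hand partition: utr5 = [100,150) = 50; cds = [150,200)+[300,400) = 150;
  ## utr3 = [400,500) = 100; intron = [200,300) = 100
  expect_equal(w(gm$utr5), 50)
  expect_equal(w(gm$cds), 150)
  expect_equal(w(gm$utr3), 100)
  expect_equal(w(gm$introns), 100)
  expect_equal(w(gm$utr5) + w(gm$cds) + w(gm$utr3), w(gm$exons))
  expect_equal(gm$downstream_ext, c(500L, 1500L))
})

test_that("degenerate and malformed annotation inputs are handled", {
  ## single-exon gene, thick covers everything -> pure CDS
  gm <- gene_model("g1", "chr1", "+", rbind(c(0L, 300L)), c(0L, 300L))
  expect_equal(nrow(gm$utr5), 0)
  expect_equal(nrow(gm$utr3), 0)
  expect_equal(gm$cds, gm$exons, ignore_attr = TRUE)
  ## noncoding gene: whole-exon noncoding region
  gn <- gene_model("g2", "chr1", "+", rbind(c(0L, 300L)), NULL)
  expect_false(gn$coding)
  expect_equal(gn$noncoding, gn$exons, ignore_attr = TRUE)
  ## overlapping exons rejected
  expect_error(gene_model("g3", "chr1", "+", rbind(c(0L, 100L), c(50L, 200L)), NULL),
               "overlapping exons")
  ## malformed BED12 reported by line
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500\tgA\t0\t+\t150\t400\t0\t2\t100,200\t0,200",
               "chr1\t10\t20\tbad"), bed)
  expect_error(load_gene_models(bed, "bed12"), "line 2")
})

test_that("GTF loading matches the equivalent BED12 model", {
  gtf <- tempfile(fileext = ".gtf")
  attrs <- 'gene_id "gA"; transcript_id "gA.1";'
  writeLines(c(
    paste("chr1", "test", "exon", 101, 200, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "test", "exon", 301, 500, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "test", "CDS", 151, 200, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "test", "CDS", 301, 400, ".", "+", ".", attrs, sep = "\t")), gtf)
  gm <- load_gene_models(gtf, "gtf", downstream = 1000L)[["gA"]]
  ref <- fix_gene_plus()
  expect_equal(gm$exons, ref$exons, ignore_attr = TRUE)
  expect_equal(gm$cds, ref$cds, ignore_attr = TRUE)
  expect_equal(gm$utr5, ref$utr5, ignore_attr = TRUE)
  expect_equal(gm$utr3, ref$utr3, ignore_attr = TRUE)
})

test_that("region assignment follows overlap and precedence rules", {
  gm <- fix_gene_plus()
  ## entirely within utr3
  expect_equal(assign_region(ginterval("chr1", 410, 430, "+"), gm), "UTR3")
  ## spanning the CDS exon/intron boundary
  iv <- ginterval("chr1", 190, 210, "+")
  expect_setequal(assign_region(iv, gm, "non_exclusive"), c("CDS", "intron"))
  expect_equal(assign_region(iv, gm, "exclusive"), "CDS")
  ## downstream of the 3' end (within the 10 kb-type extension)
  gm10 <- gene_model("gP", "chr1", "+", rbind(c(100L, 200L), c(300L, 500L)),
                     c(150L, 400L), 10000L)
  expect_equal(assign_region(ginterval("chr1", 5500, 5520, "+"), gm10), "downstream")
  ## outside everything
  expect_equal(assign_region(ginterval("chr1", 50000, 50010, "+"), gm10), "none")
  ## zero-length interval rejected at construction
  expect_error(ginterval("chr1", 10, 10, "+"), "invalid interval")
})

test_that("minus-strand gene mirrors the plus-strand one exactly", {
  gp <- fix_gene_plus(); gmn <- fix_gene_minus()
  mirror <- function(s, e) c(2600L - e, 2600L - s)  # reflect [s,e) about 2600
  w <- function(m) sum(m[, 2] - m[, 1])
  ## utr3 lies at the lower genomic coordinates on the minus strand
  expect_lt(max(gmn$utr3[, 2]), min(gmn$cds[, 1]) + 1)
  expect_equal(w(gmn$utr5), w(gp$utr5))
  expect_equal(w(gmn$utr3), w(gp$utr3))
  ## strand-flip oracle: every interval's labels match its mirrored image
  set.seed(7)
  for (i in 1:50) {
    s <- sample(0:1600, 1L); len <- sample(1:120, 1L)
    lp <- tryCatch(assign_region(ginterval("chr1", s, s + len, "+"), gp,
                                 "non_exclusive"), error = function(e) NULL)
    m <- mirror(s, s + len)
    lm <- tryCatch(assign_region(ginterval("chr1", m[1], m[2], "-"), gmn,
                                 "non_exclusive"), error = function(e) NULL)
    expect_equal(sort(lp), sort(lm))
  }
})

test_that("partition and superset invariants hold on random gene models", {
  set.seed(11)
  w <- function(m) sum(m[, 2] - m[, 1])
  for (i in 1:30) {
    n_ex <- sample(1:4, 1L)
    bounds <- sort(sample(0:2000, 2L * n_ex))
    exons <- matrix(bounds, ncol = 2L, byrow = TRUE)
    exons <- exons[exons[, 2] > exons[, 1], , drop = FALSE]
    if (nrow(exons) == 0L) next
    tx <- range(exons)
    thick <- sort(sample(seq(tx[1], tx[2]), 2L))
    gm <- gene_model("gr", "chr1", sample(c("+", "-"), 1L), exons,
                     if (thick[2] > thick[1]) thick else NULL)
    if (gm$coding)
      expect_equal(w(gm$utr5) + w(gm$cds) + w(gm$utr3), w(gm$exons))
    ## non-exclusive labels are a superset of the exclusive label
    s <- sample(seq(tx[1], tx[2] + 500L), 1L)
    iv <- ginterval("chr1", s, s + 25L, gm$strand)
    expect_true(assign_region(iv, gm, "exclusive") %in%
                  c(assign_region(iv, gm, "non_exclusive")))
  }
})

test_that("distance to transcript end is signed and strand-aware", {
  gm <- fix_gene_plus()   # 3' end at base 499
  ## 20-nt interval [480,500): midpoint rounds to base 489 -> -10
  expect_equal(distance_to_transcript_end(ginterval("chr1", 480, 500, "+"), gm), -10)
  ## midpoint exactly at the 3'-terminal base
  expect_equal(distance_to_transcript_end(ginterval("chr1", 499, 500, "+"), gm), 0)
  ## minus strand: 3' end at tx_start; lower coordinates are downstream
  gmn <- fix_gene_minus() # 3' end at base 2100
  expect_equal(distance_to_transcript_end(ginterval("chr1", 2099, 2100, "-"), gmn), 1)
  expect_gt(distance_to_transcript_end(ginterval("chr1", 2060, 2080, "-"), gmn), 0)
  ## strand-flip oracle: mirrored interval has the same offset
  d_plus <- distance_to_transcript_end(ginterval("chr1", 470, 490, "+"), gm)
  d_minus <- distance_to_transcript_end(ginterval("chr1", 2110, 2130, "-"), gmn)
  expect_equal(d_plus, d_minus)
})
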