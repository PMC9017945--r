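toy_len <- c(chr1 = 100000L)

test_that("deduplication keeps one representative per sequence", {
  rd <- make_reads("chr1", c(1L, 1L, 5L), "+",
                   c("ACGTACGT", "ACGTACGT", "ACGTACGA"))
  dd <- deduplicate(rd)
  expect_equal(nrow(dd), 2L)
  expect_equal(attr(dd, "n_removed"), 1L)
  # reads differing only in terminal random bases stay distinct
  rd2 <- make_reads("chr1", 1L, "+", c("AAACGTACGTTT", "CCACGTACGTGG"))
  expect_equal(nrow(deduplicate(rd2)), 2L)
  expect_equal(nrow(deduplicate(rd[0, ])), 0L)
})

test_that("size binning respects the range and conserves fractions", {
  rd <- make_reads("chr1", 1L, "+",
                   c(strrep("A", 24), strrep("C", 24), strrep("G", 21),
                     strrep("T", 19), strrep("A", 30)))
  b <- bin_by_size(rd)
  expect_equal(b$fractions$n[b$fractions$size == 24], 2L)
  expect_equal(b$fractions$n[b$fractions$size == 21], 1L)
  expect_equal(sum(b$fractions$n), 3L)           # 19 and 30 nt in no bin
  expect_equal(sum(b$fractions$fraction), 3 / 5)  # denominator = all reads
  b2 <- bin_by_size(rd, denominator = "in_range")
  expect_equal(sum(b2$fractions$fraction), 1)
  expect_error(bin_by_size(rd, min = 24, max = 21), "min")
  # all reads one size: fraction 1
  rd24 <- make_reads("chr1", 1L, "+", rep(strrep("A", 24), 10))
  expect_equal(bin_by_size(rd24)$fractions$fraction[4], 1)
})

test_that("window tiling arithmetic matches the sliding-window dialects", {
  win <- endopoe:::tile_windows(c(chr1 = 1000L), 300, 100)
  expect_length(win, 8)  # starts 0,100,...,700 in 0-based terms
  expect_equal(GenomicRanges::start(win), seq(1L, 701L, by = 100L))
  expect_equal(unique(GenomicRanges::width(win)), 300L)
  expect_error(endopoe:::tile_windows(c(chr1 = 1000L), 0, 100), "positive")
})

test_that("overlap mode counts a read in every covering window", {
  # read with 5' coordinate 150 (0-based) = 151 internal: windows starting
  # at 0 and 100
  rd <- make_reads("chr1", 151L, "+", strrep("A", 24))
  cs <- count_windows(rd, c(chr1 = 1000L), 300, 100, mode = "overlap")
  hit <- cs$counts[, 1] > 0
  expect_equal(cs$features$start[hit], c(1L, 101L))
  expect_equal(sum(cs$counts), 2)
})

test_that("assign mode conserves the library total", {
  sim <- small_sim()
  rd <- simulate_srna_reads(sim, "WT", 1)
  cs <- count_windows(rd, sim$genome, 300, 100, mode = "assign")
  expect_equal(sum(cs$counts), nrow(rd))
  cs0 <- count_windows(rd[0, ], sim$genome, 300, 100)
  expect_true(all(cs0$counts == 0))
})

test_that("feature counting uses the 5'-start containment tie rule", {
  feats <- make_granges("chr1", c(101L, 301L), c(400L, 600L),
                        id = c("geneA", "teB"), class = c("gene", "TE"))
  rd <- make_reads("chr1", c(150L, 390L, 390L, 50L),
                   c("+", "+", "-", "+"), strrep("A", 24))
  # read 3 is minus-strand: 5' end at 390+23=413, inside teB only
  cs <- count_features(rd, feats)
  expect_equal(cs$counts["geneA", 1], 2)
  expect_equal(cs$counts["teB", 1], 1)
  expect_equal(sum(cs$counts), 3)  # read at 50 is intergenic
})

test_that("cluster calling merges, filters by rpm and classifies size", {
  mk <- function(n, len, at) make_reads("chr1", at, "+",
                                        rep(strrep("A", len), n))
  rd <- rbind(mk(60, 24, 500L), mk(30, 23, 520L), mk(10, 21, 540L))
  cl <- call_clusters(rd, library_size = 1e6)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$total, 100)
  expect_equal(cl$dicer_fraction, 1.0)
  expect_equal(cl$predominant_size, "24")
  # tied mode with dicer fraction exactly 0.8 -> none
  rd2 <- rbind(mk(40, 24, 500L), mk(40, 21, 520L), mk(20, 33, 540L))
  cl2 <- call_clusters(rd2, library_size = 1e6)
  expect_equal(cl2$dicer_fraction, 0.8)
  expect_equal(cl2$predominant_size, "none")
  # 1 read in a 2M library is exactly 0.5 rpm and is retained (>=)
  cl3 <- call_clusters(mk(1, 24, 100L), library_size = 2e6)
  expect_equal(cl3$rpm, 0.5)
  expect_equal(nrow(cl3), 1L)
  expect_error(call_clusters(rd, library_size = 0), "positive")
})

test_that("islands closer than pad merge; clusters never double count", {
  mk <- function(n, at) make_reads("chr1", at, "+",
                                   rep(strrep("A", 24), n))
  rd <- rbind(mk(5, 100L), mk(5, 170L), mk(5, 400L))
  cl <- call_clusters(rd, library_size = 1e6, pad = 75)
  expect_equal(nrow(cl), 2L)     # 100/170 merge (gap 70 < 75), 400 apart
  expect_equal(sum(cl$total), nrow(rd))
  cl2 <- call_clusters(rd, library_size = 1e6, pad = 50)
  expect_equal(nrow(cl2), 3L)
})

test_that("multimapper weighting needs nearby unique starts", {
  mk <- function(at, hits) make_reads("chr1", at, "+", strrep("A", 24),
                                      n_hits = hits)
  rd <- rbind(mk(100L, 1L), mk(120L, 2L), mk(5000L, 2L))
  un <- call_clusters(rd, library_size = 1e6, multimapper = "unique")
  expect_equal(sum(un$total), 1)
  wt <- call_clusters(rd, library_size = 1e6, multimapper = "weighted")
  # the supported multimapper contributes 1/2; the isolated one nothing
  expect_equal(sum(wt$total), 1.5)
})

test_that("clusters recover expressed simulated loci and vanish in null", {
  sim <- small_sim()
  wt <- simulate_srna_reads(sim, "WT", 1)
  # desk-scale libraries: mincov equivalent to ~5 reads (0.5 rpm at the
  # study's multi-million-read depth)
  mincov <- 1e6 * 5 / nrow(wt)
  cl <- call_clusters(wt, library_size = nrow(wt), mincov_rpm = mincov)
  cl_gr <- GenomicRanges::GRanges(cl$chrom,
                                  IRanges::IRanges(cl$start, cl$end))
  loci <- sim$truth$loci
  expressed <- loci$mean_reads >= 5
  loci_gr <- GenomicRanges::GRanges(loci$chrom,
                                    IRanges::IRanges(loci$start, loci$end))
  hit <- GenomicRanges::countOverlaps(loci_gr[expressed], cl_gr) > 0
  expect_gte(mean(hit), 0.95)
  # null library: Pol IV-dependent loci collapse to the background floor
  # (the qualitative peak-absence behavior; residual reads are uniform
  # background, so depletion is assessed on per-locus coverage)
  nl <- simulate_srna_reads(sim, "null", 1)
  locus_cov <- function(reads) {
    fp <- endopoe:::five_prime(reads)
    GenomicRanges::countOverlaps(
      loci_gr, GenomicRanges::GRanges(reads$chrom,
                                      IRanges::IRanges(fp, fp)))
  }
  cov_wt <- locus_cov(wt)
  cov_null <- locus_cov(nl)
  dep <- loci$class %in% c("polIV_gene", "polIV_te", "isr_mat", "isr_pat")
  lost <- cov_null[dep & expressed] <= 0.1 * cov_wt[dep & expressed]
  expect_gte(mean(lost), 0.95)
  # miRNA loci keep their clusters in the null
  cln <- call_clusters(nl, library_size = nrow(nl),
                       mincov_rpm = 1e6 * 5 / nrow(nl))
  cln_gr <- GenomicRanges::GRanges(cln$chrom,
                                   IRanges::IRanges(cln$start, cln$end))
  mir <- loci$class == "mirna"
  expect_gte(mean(GenomicRanges::countOverlaps(loci_gr[mir], cln_gr) > 0),
             0.8)
})
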