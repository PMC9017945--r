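# genome crafted so every context appears on both strands:
# pos: 123456789...
ctx_genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTCATCAGCCGATTGTTT"))
# '+' strand Cs: 2 (CGT->CG), 5 (CAT->CHH), 8 (CAG->CHG), 11 (CCG->CHG),
#               12 (CGA->CG)
# '-' strand Gs: 3 (revcomp(ACG)=CGT->CG), 10 (revcomp(CAG)=CTG->CHG),
#               13 (revcomp(CCG)=CGG->CG), 17 (revcomp(TTG)=CAA->CHH)

mk_calls <- function(pos, strand, m, t, allele = "ambiguous",
                     chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = NA_character_, n_meth = as.integer(m),
             n_total = as.integer(t), allele = allele)
}

test_that("context labeling follows the strand-appropriate trinucleotide", {
  calls <- mk_calls(c(2, 5, 8, 11, 3, 10, 13, 17),
                    c("+", "+", "+", "+", "-", "-", "-", "-"), 0, 10)
  out <- pileup_contexts(calls, ctx_genome)
  expect_equal(out$context,
               c("CG", "CHH", "CHG", "CHG", "CG", "CHG", "CG", "CHH"))
})

test_that("calls at non-cytosines error; contig-end contexts are dropped", {
  expect_error(pileup_contexts(mk_calls(1, "+", 0, 5), ctx_genome),
               "non-cytosine")
  # '+' C at position 19 of a 20-bp contig: context undeterminable
  g <- Biostrings::DNAStringSet(c(chr1 = "AAAAAAAAAAAAAAAAAACA"))
  out <- pileup_contexts(mk_calls(19, "+", 0, 5), g)
  expect_equal(nrow(out), 0L)
})

test_that("conversion QC uses depth-qualified chloroplast cytosines", {
  calls <- rbind(mk_calls(1:100, "+", 0, 10, chrom = "chrC"),
                 mk_calls(101, "+", 10, 10, chrom = "chrC"))
  calls$context <- "CHH"
  # 10 methylated of 1010 total -> 99.0%
  qc <- conversion_qc(calls, "chrC", min_depth = 10)
  expect_equal(qc$conversion_rate, 100 * (1 - 10 / 1010))
  expect_true(qc$pass)
  # a depth-9 cytosine, fully methylated, must not move the estimate
  calls2 <- rbind(calls, transform(mk_calls(102, "+", 9, 9, chrom = "chrC"),
                                   context = "CHH"))
  expect_equal(conversion_qc(calls2, "chrC")$conversion_rate,
               qc$conversion_rate)
  expect_error(conversion_qc(calls[0, ], "chrC"), "chloroplast")
})

test_that("window methylation is the coverage-weighted percent", {
  # 4 common informative CHH cytosines in one window
  a <- mk_calls(c(10, 20, 30, 40), "+", c(2, 0, 5, 3), 10)
  a$context <- "CHH"
  b <- mk_calls(c(10, 20, 30, 40), "+", c(1, 1, 1, 1), 8)
  b$context <- "CHH"
  jt <- methyl_join(a, b)
  win <- window_methylation(jt, c(chr1 = 300L), window = 300, step = 300)
  expect_equal(nrow(win), 1L)
  expect_equal(win$percent_a, 25.0)
  expect_equal(win$n_common, 4)
  # fewer than 3 common informative cytosines: excluded
  jt2 <- jt[1:2, ]
  expect_equal(nrow(window_methylation(jt2, c(chr1 = 300L), 300, 300)), 0L)
  # identical inputs give delta 0 everywhere
  jt3 <- methyl_join(a, a)
  win3 <- window_methylation(jt3, c(chr1 = 300L), 300, 300)
  expect_equal(win3$delta, 0)
})

test_that("cytosines informative in only one condition are excluded", {
  a <- mk_calls(c(10, 20, 30, 40), "+", c(10, 0, 0, 0), 10)
  a$context <- "CHH"
  b <- mk_calls(c(20, 30, 40, 50), "+", 0, 10)
  b$context <- "CHH"
  jt <- methyl_join(a, b)
  expect_equal(jt$pos, c(20L, 30L, 40L))  # 10 and 50 are one-sided
})

test_that("the dosage filter keeps the 52-82 percent band inclusively", {
  win <- data.frame(chrom = "chr1", start = c(1, 101, 201, 301),
                    end = c(300, 400, 500, 600), context = "CHH",
                    delta = 0)
  dosage <- data.frame(chrom = "chr1", start = c(1, 101, 201, 301),
                       percent_maternal = c(67, 90, 52, NA))
  out <- dosage_filter(win, dosage)
  expect_equal(out$start, c(1, 201))  # 67 in, 52 boundary in, 90 out,
                                      # NA (no informative reads) out
  expect_equal(nrow(dosage_filter(win[2, ], dosage[2, ], center = 67,
                                  tolerance = 25)), 1L)
})

test_that("window dosage reflects allele-resolved depth", {
  calls <- rbind(mk_calls(c(10, 20), "+", 0, 20, allele = "maternal"),
                 mk_calls(c(30,  40), "+", 0, 10, allele = "paternal"),
                 mk_calls(50, "+", 0, 99, allele = "ambiguous"))
  d <- window_dosage(calls, c(chr1 = 300L), 300, 300)
  expect_equal(d$percent_maternal, 100 * 40 / 60)
})

test_that("replicate-variable windows are masked out of DMR calls", {
  win_rep <- data.frame(chrom = "chr1", start = c(1, 101), end = c(300, 400),
                        context = "CHH", delta = c(25, 3))
  mask <- replicate_mask(win_rep)
  expect_length(mask, 1)
  expect_equal(GenomicRanges::start(mask), 1L)
  # identical replicates -> empty mask
  win_same <- transform(win_rep, delta = 0)
  expect_length(replicate_mask(win_same), 0)
})

test_that("DMR thresholds are context-specific and windows merge by overlap", {
  jt <- data.frame(chrom = "chr1", pos = c(50, 150, 250, 350),
                   strand = "+", context = "CHH",
                   m_a = c(20, 20, 20, 20), t_a = 100,
                   m_b = c(5, 5, 5, 20), t_b = 100)
  win <- data.frame(chrom = "chr1", start = c(1, 101, 201),
                    end = c(300, 400, 500), context = "CHH",
                    delta = c(-15, -15, -10),
                    percent_a = 20, percent_b = c(5, 5, 10))
  dmr <- call_dmrs(win, jt)
  expect_equal(nrow(dmr), 1L)           # overlapping hypo windows merge
  expect_equal(dmr$start, 1L)
  expect_equal(dmr$end, 500L)
  expect_equal(dmr$direction, "hypo")
  expect_equal(dmr$n_windows, 3L)
  # CG needs a 30-point difference: 25 is not enough
  win_cg <- transform(win[1, ], context = "CG", delta = -25)
  expect_equal(nrow(call_dmrs(win_cg, transform(jt, context = "CG"))), 0L)
  # CHH at 15 points qualifies (threshold 10)
  expect_equal(nrow(call_dmrs(win[1, ], jt)), 1L)
  # masked regions never reach the output
  msk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500),
                                context = "CHH")
  expect_equal(nrow(call_dmrs(win, jt, mask = msk)), 0L)
})

test_that("swapping conditions flips DMR direction and nothing else", {
  jt <- data.frame(chrom = "chr1", pos = c(50, 150, 250), strand = "+",
                   context = "CHH", m_a = 30, t_a = 100, m_b = 5,
                   t_b = 100)
  win <- window_methylation(jt, c(chr1 = 600L), 300, 100, min_depth = 0)
  jt_sw <- transform(jt, m_a = jt$m_b, t_a = jt$t_b, m_b = jt$m_a,
                     t_b = jt$t_a)
  win_sw <- window_methylation(jt_sw, c(chr1 = 600L), 300, 100,
                               min_depth = 0)
  d1 <- call_dmrs(win, jt)
  d2 <- call_dmrs(win_sw, jt_sw)
  expect_equal(d1$start, d2$start)
  expect_equal(d1$end, d2$end)
  expect_true(all(d1$direction == "hypo"))
  expect_true(all(d2$direction == "hyper"))
  expect_equal(d1$percent_a, d2$percent_b)
})

test_that("DMR output is invariant to window enumeration order", {
  jt <- data.frame(chrom = "chr1", pos = c(50, 150, 250, 1050), strand = "+",
                   context = "CHH", m_a = 30, t_a = 100, m_b = 5,
                   t_b = 100)
  win <- window_methylation(jt, c(chr1 = 1500L), 300, 100, min_depth = 0)
  d1 <- call_dmrs(win, jt)
  d2 <- call_dmrs(win[rev(seq_len(nrow(win))), ], jt)
  expect_equal(d1, d2)
})

test_that("planted CHH-loss regions are recovered at simulated depth", {
  sim <- small_sim()
  wt <- rbind(simulate_methylome(sim, "WT", 1),
              simulate_methylome(sim, "WT", 2))
  mh <- rbind(simulate_methylome(sim, "mat_het", 1),
              simulate_methylome(sim, "mat_het", 2))
  jt <- methyl_join(wt, mh)
  win <- window_methylation(jt, sim$genome)
  dmr <- call_dmrs(win, jt)
  dmr <- dmr[dmr$context == "CHH", ]
  truth <- sim$truth$loci[sim$truth$loci$class == "isr_mat", ]
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start, truth$end))
  dg <- GenomicRanges::GRanges(dmr$chrom,
                               IRanges::IRanges(dmr$start, dmr$end))
  # reciprocal overlap >= 50%
  hits <- GenomicRanges::findOverlaps(tg, dg)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    tg[S4Vectors::queryHits(hits)], dg[S4Vectors::subjectHits(hits)]))
  good <- ov >= 0.5 * GenomicRanges::width(tg[S4Vectors::queryHits(hits)]) &
    ov >= 0.5 * GenomicRanges::width(dg[S4Vectors::subjectHits(hits)])
  recall <- length(unique(S4Vectors::queryHits(hits)[good])) / length(tg)
  precision <- length(unique(S4Vectors::subjectHits(hits)[good])) /
    length(dg)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  expect_true(all(dmr$direction == "hypo"))
})
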