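test_that("the generator is deterministic and streams are independent", {
  cfg <- small_config(seed = 99)
  s1 <- simulate_genome_and_snps(cfg)
  s2 <- simulate_genome_and_snps(cfg)
  expect_equal(as.character(s1$genome), as.character(s2$genome))
  expect_equal(s1$snps$pos, s2$snps$pos)
  expect_equal(s1$truth$genes, s2$truth$genes)
  r1 <- simulate_srna_reads(s1, "WT", 1)
  r2 <- simulate_srna_reads(s2, "WT", 1)
  expect_equal(r1, r2)
  # a different replicate gives a different draw from its own stream
  r3 <- simulate_srna_reads(s1, "WT", 2)
  expect_false(identical(r1$sequence, r3$sequence))
  # global RNG state is untouched
  set.seed(42); before <- runif(3)
  simulate_srna_reads(s1, "WT", 1)
  set.seed(42)
  expect_equal(runif(3), before)
})

test_that("SNP placement follows the configured rate and constraints", {
  cfg <- small_config(seed = 7, snp_rate = 0)
  expect_equal(nrow(simulate_genome_and_snps(cfg)$snps), 0L)
  # 200-kb contig at 1/200: expect 1000 within 4 SD (binomial bounds)
  cfg2 <- sim_config(seed = 7, n_contigs = 1, contig_bp = 200000L,
                     snp_rate = 1 / 200, chloroplast_bp = 10000L,
                     n_genes = 10L, n_tes = 5L, n_mirna = 2L,
                     n_isr_mat = 2L, n_isr_pat = 2L, n_antagonistic = 2L,
                     n_mat_effect = 2L, n_pat_effect = 2L,
                     n_both_parent = 2L, n_meg = 1L, n_peg = 1L)
  snps <- simulate_genome_and_snps(cfg2)$snps
  sd4 <- 4 * sqrt(200000 * (1 / 200) * (1 - 1 / 200))
  expect_lt(abs(nrow(snps) - 1000), sd4)
  # never adjacent, never on the chloroplast, REF matches the genome
  expect_true(all(diff(snps$pos[snps$chrom == "chr1"]) > 1))
  expect_false(any(snps$chrom == cfg2$chloroplast_name))
  sim2 <- simulate_genome_and_snps(cfg2)
  have <- substring(as.character(sim2$genome[["chr1"]]), snps$pos,
                    snps$pos)
  expect_equal(have, snps$ref)
})

test_that("locus panels that cannot be placed are a hard error", {
  cfg <- small_config(n_genes = 1000L, gene_bp = 600L)
  expect_error(simulate_genome_and_snps(cfg), "panel")
})

test_that("unknown genotype labels are rejected", {
  sim <- small_sim()
  expect_error(simulate_srna_reads(sim, "het"), "genotype")
  expect_error(simulate_methylome(sim, "wt"), "genotype")
})

test_that("sRNA genotype rules match the parental-memory model", {
  sim <- small_sim()
  loci <- sim$truth$loci
  lgr <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start, loci$end))
  count_at <- function(reads, cls, allele = NULL) {
    ids <- loci$locus_id[loci$class %in% cls]
    if (!is.null(allele)) reads <- reads[reads$true_allele == allele, ]
    sum(reads$source %in% ids)
  }
  wt <- simulate_srna_reads(sim, "WT", 1)
  null <- simulate_srna_reads(sim, "null", 1)
  mat <- simulate_srna_reads(sim, "mat_het", 1)
  pat <- simulate_srna_reads(sim, "pat_het", 1)
  # Pol IV-dependent loci emit zero non-background reads in the null
  dep <- c("polIV_gene", "polIV_te", "isr_mat", "isr_pat")
  expect_equal(count_at(null, dep), 0)
  # miRNA loci are genotype-independent
  expect_gt(count_at(null, "mirna") / count_at(wt, "mirna"), 0.5)
  # maternal-memory loci: maternal reads silent in mat_het, at WT level
  # in pat_het
  m_wt <- count_at(wt, "isr_mat", "maternal")
  expect_equal(count_at(mat, "isr_mat", "maternal"), 0)
  expect_gt(count_at(pat, "isr_mat", "maternal") / m_wt, 0.5)
  # paternal-memory loci are symmetric
  p_wt <- count_at(wt, "isr_pat", "paternal")
  expect_equal(count_at(pat, "isr_pat", "paternal"), 0)
  expect_gt(count_at(mat, "isr_pat", "paternal") / p_wt, 0.5)
})

test_that("WT allele-assignable sRNAs at biallelic loci match the bias", {
  sim <- small_sim()
  rd <- simulate_srna_reads(sim, "WT", 1)
  loci <- sim$truth$loci
  bial <- loci$class %in% c("polIV_gene", "polIV_te")
  lgr <- GenomicRanges::GRanges(loci$chrom[bial],
                                IRanges::IRanges(loci$start[bial],
                                                 loci$end[bial]))
  fp <- endopoe:::five_prime(rd)
  inside <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(rd$chrom, IRanges::IRanges(fp, fp)), lgr) > 0
  al <- assign_allele(rd[inside, ], sim$snps, sim$genome)
  m <- sum(al == "maternal"); p <- sum(al == "paternal")
  bias <- sim$config$biallelic_bias
  expect_lt(abs(m / (m + p) - bias),
            3 * sqrt(bias * (1 - bias) / (m + p)))
})

test_that("mRNA means are additive and allelic split recovers dosage", {
  sim <- small_sim()
  g <- sim$truth$genes
  # exact additivity in the noiseless means
  mu <- function(mm, fm) 2^(g$beta0 + g$beta_mat * mm + g$beta_pat * fm)
  expect_equal(log2(mu(TRUE, TRUE)) - log2(mu(FALSE, FALSE)),
               g$beta_mat + g$beta_pat)
  mr <- simulate_mrna_counts(sim, n_reps = 2)
  # genes with no effect share one mean across genotypes
  none <- g$panel == "none"
  m_by_gt <- vapply(GENOTYPES <- c("WT", "mat_het", "pat_het", "null"),
                    function(gt) mean(mr$total$counts[
                      none, mr$total$samples$genotype == gt]), 0)
  expect_lt(max(m_by_gt) / min(m_by_gt), 1.1)
  # non-imprinted genes: mean maternal fraction ~ 2/3
  wt_cols <- mr$total$samples$genotype == "WT"
  msum <- rowSums(mr$maternal$counts[, wt_cols, drop = FALSE])
  psum <- rowSums(mr$paternal$counts[, wt_cols, drop = FALSE])
  frac <- (msum / (msum + psum))[g$imprint == "none"]
  expect_lt(abs(mean(frac, na.rm = TRUE) - 2 / 3), 0.02)
  # imprinted genes sit near their extremes
  expect_gt(mean(msum / (msum + psum), na.rm = TRUE)[1], 0)  # guard
  expect_true(all((msum / (msum + psum))[g$imprint == "MEG"] > 0.8))
  expect_true(all((msum / (msum + psum))[g$imprint == "PEG"] < 0.2))
})

test_that("methylome conversion failure and dosage behave as configured", {
  sim <- small_sim()
  # perfect conversion and true p = 0 gives zero methylated calls
  cfg_perfect <- small_config(seed = 12, conversion_rate = 1)
  simp <- simulate_genome_and_snps(cfg_perfect)
  mep <- simulate_methylome(simp, "WT", 1)
  chl <- mep$chrom == cfg_perfect$chloroplast_name
  expect_equal(sum(mep$n_meth[chl]), 0L)
  # 99% conversion leaves ~1% apparent chloroplast methylation
  me <- simulate_methylome(sim, "WT", 1)
  chl2 <- me$chrom == sim$config$chloroplast_name
  apparent <- sum(me$n_meth[chl2]) / sum(me$n_total[chl2])
  expect_lt(abs(apparent - 0.01), 0.003)
  # allele-resolved DNA reads recover the 2/3 maternal dosage
  m <- sum(me$n_total[me$allele == "maternal"])
  p <- sum(me$n_total[me$allele == "paternal"])
  expect_lt(abs(m / (m + p) - 2 / 3), 0.01)
})

test_that("5'-end tracks conserve spikes plus noise and track genotype", {
  sim <- small_sim()
  np <- simulate_nanopare(sim, genotypes = c("WT", "null"), n_reps = 2)
  expect_equal(nrow(np$counts),
               nrow(np$features))
  # cleavage sites are empty in every null replicate
  clv <- np$features$site_type == "cleavage"
  null_cols <- np$samples$genotype == "null"
  expect_equal(sum(np$counts[clv, null_cols]), 0)
  expect_gt(sum(np$counts[clv, !null_cols]), 0)
  # TSS spikes scale with the gene's expression change
  g <- sim$truth$genes
  up <- g$gene_id[g$beta_mat + g$beta_pat > 1]
  ti <- np$features$site_type == "tss" & np$features$gene_id %in% up
  expect_gt(sum(np$counts[ti, null_cols]), sum(np$counts[ti, !null_cols]))
})
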