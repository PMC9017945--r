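#' Simulation configuration
#'
#' Defaults describe a desk-scale endosperm experiment: two 200-kb nuclear
#' contigs plus a 150-kb chloroplast, Col/Ler-density SNPs, ~400 genes,
#' ~200 TEs, 20 miRNA loci, 30 maternally and 30 paternally imprinted sRNA
#' regions, 100k sRNA reads per library and 30x methylome depth, with the
#' triploid 2 maternal : 1 paternal genome dosage built into every
#' DNA-derived quantity. Effect sizes are drawn on the log2 scale from
#' `beta_range`; the antagonistic gene panel plants
#' `beta_pat = -antagonism_ratio * beta_mat`.
#'
#' @param seed master integer seed; every library derives its own stream
#'   from it (see [stream_seed()]), so adding a library never perturbs
#'   existing ones.
#' @param ... overrides for any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # genome geometry
    n_contigs = 2, contig_bp = 200000L, chloroplast_bp = 150000L,
    chloroplast_name = "chrC",
    snp_rate = 1 / 150,
    # locus panels (placed without overlap within each class)
    n_genes = 400L, gene_bp = 600L,
    n_tes = 200L, te_bp = 400L,
    n_mirna = 20L, mirna_bp = 150L,
    n_isr_mat = 30L, n_isr_pat = 30L, isr_bp = 400L,
    # sRNA libraries
    srna_reads = 100000L, background_frac = 0.05,
    srna_size_probs = c("21" = 0.08, "22" = 0.04, "23" = 0.08,
                        "24" = 0.80),
    mirna_size_probs = c("21" = 0.90, "22" = 0.10),
    srna_dispersion = 0.1,
    biallelic_bias = 2 / 3, mat_isr_bias = 0.95, pat_isr_bias = 0.05,
    frac_genes_srna = 0.25,
    # mRNA libraries
    mrna_dispersion = 0.05, mrna_baseline_log2 = c(4, 9),
    n_antagonistic = 60L, n_mat_effect = 80L, n_pat_effect = 30L,
    n_both_parent = 30L,
    beta_range = c(1.5, 3), antagonism_ratio = 1,
    n_meg = 40L, n_peg = 20L,
    mrna_info_frac = 0.3, allelic_concentration = 300,
    # methylomes
    depth = 30, conversion_rate = 0.99,
    meth_background = c(CG = 0.20, CHG = 0.08, CHH = 0.03),
    chh_rddm = 0.30, chh_lost = 0.05,
    meth_assignable_frac = 0.4,
    # 5'-end (NanoPARE-style) tracks
    nanopare_tss_scale = 0.1, nanopare_cleavage_mean = 50,
    n_cleavage_genes = 20L, nanopare_noise_sites = 500L,
    nanopare_noise_mean = 0.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stopf("unknown sim_config field: %s", unknown[1])
  cfg[names(dots)] <- dots
  structure(cfg, class = c("sim_config", "list"))
}

# non-overlapping placement of n intervals of width w on [1, L]
place_intervals <- function(n, w, L) {
  if (n == 0) return(integer(0))
  free <- L - n * w
  if (free < 0)
    stopf(paste("cannot place %d loci of %d bp on a %d-bp contig without",
                "overlap; reduce the panel size"), n, w, L)
  gaps <- sort(floor(stats::runif(n, 0, free + 1)))
  as.integer(gaps + (seq_len(n) - 1L) * w + 1L)
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# split n loci across contigs proportionally to length
split_counts <- function(n, lens) {
  raw <- floor(n * lens / sum(lens))
  left <- n - sum(raw)
  if (left > 0) raw[seq_len(left)] <- raw[seq_len(left)] + 1L
  raw
}

#' Simulate the genome, SNPs, annotations and ground truth
#'
#' Builds a uniform-random nuclear genome plus an unmethylated, SNP-free
#' chloroplast contig; places SNPs by Bernoulli(`snp_rate`) per position
#' (avoiding adjacent positions); places gene/TE/miRNA/ISR panels without
#' within-class overlap; and fixes every latent parameter downstream
#' generators use (per-locus sRNA means and allelic bias, per-gene
#' maternal/paternal effects and imprinting status, per-cytosine
#' methylation regime). The reference frame is the paternal (Col-0-like)
#' genome; alternate SNP alleles are maternal (Ler-like).
#'
#' @param config a [sim_config()].
#' @return A list of class `endosperm_sim`: `genome`, `maternal_genome`,
#'   `snps`, `features` (a `GRanges`), `truth` (per-locus, per-gene and
#'   per-cytosine latent parameters plus `dosage = 2/3`), `config`.
#' @export
simulate_genome_and_snps <- function(config = sim_config()) {
  cfg <- config
  with_stream(stream_seed(cfg$seed, "genome"), {
    contigs <- sprintf("chr%d", seq_len(cfg$n_contigs))
    seqs <- vapply(contigs, function(x) random_sequence(cfg$contig_bp), "")
    seqs[cfg$chloroplast_name] <- random_sequence(cfg$chloroplast_bp)
    genome <- Biostrings::DNAStringSet(seqs)

    # SNPs: nuclear contigs only, never at adjacent positions
    snp_list <- lapply(contigs, function(ctg) {
      pos <- which(stats::runif(cfg$contig_bp) < cfg$snp_rate)
      if (length(pos) > 1) pos <- pos[c(TRUE, diff(pos) > 1)]
      if (length(pos) == 0)
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          parent_of_ref = character()))
      ref <- substring(seqs[ctg], pos, pos)
      alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      data.frame(chrom = ctg, pos = pos, ref = ref, alt = unname(alt),
                 parent_of_ref = "paternal")
    })
    snps <- snp_table(do.call(rbind, snp_list))
    rownames(snps) <- NULL

    # locus panels
    lens <- stats::setNames(rep(cfg$contig_bp, cfg$n_contigs), contigs)
    panel <- function(n, w, prefix) {
      per <- split_counts(n, lens)
      do.call(rbind, lapply(contigs, function(ctg) {
        st <- place_intervals(per[ctg], w, lens[ctg])
        if (length(st) == 0) return(NULL)
        data.frame(chrom = ctg, start = st, end = st + w - 1L)
      })) -> d
      d$feature_id <- sprintf("%s%03d", prefix, seq_len(nrow(d)))
      d
    }
    genes <- panel(cfg$n_genes, cfg$gene_bp, "gene")
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    tes <- panel(cfg$n_tes, cfg$te_bp, "te")
    mirna <- panel(cfg$n_mirna, cfg$mirna_bp, "mir")
    isr_m <- panel(cfg$n_isr_mat, cfg$isr_bp, "isrM")
    isr_p <- panel(cfg$n_isr_pat, cfg$isr_bp, "isrP")

    feat_df <- rbind(
      data.frame(genes[c("chrom", "start", "end", "feature_id")],
                 strand = genes$strand, feature_class = "gene"),
      data.frame(tes[c("chrom", "start", "end", "feature_id")],
                 strand = "*", feature_class = "TE"),
      data.frame(mirna[c("chrom", "start", "end", "feature_id")],
                 strand = "*", feature_class = "miRNA"),
      data.frame(isr_m[c("chrom", "start", "end", "feature_id")],
                 strand = "*", feature_class = "ISR"),
      data.frame(isr_p[c("chrom", "start", "end", "feature_id")],
                 strand = "*", feature_class = "ISR"),
      data.frame(chrom = cfg$chloroplast_name, start = 1L,
                 end = cfg$chloroplast_bp, feature_id = "chloroplast",
                 strand = "*", feature_class = "chloroplast"))
    features <- GenomicRanges::GRanges(
      feat_df$chrom, IRanges::IRanges(feat_df$start, feat_df$end),
      strand = feat_df$strand, feature_id = feat_df$feature_id,
      feature_class = feat_df$feature_class)

    # sRNA locus panel: all TEs, a subset of genes, all miRNAs, all ISRs
    n_srna_genes <- round(cfg$frac_genes_srna * nrow(genes))
    srna_gene_idx <- sort(sample(nrow(genes), n_srna_genes))
    loci <- rbind(
      data.frame(genes[srna_gene_idx, c("feature_id", "chrom", "start",
                                        "end")],
                 class = "polIV_gene", bias = cfg$biallelic_bias),
      data.frame(tes[c("feature_id", "chrom", "start", "end")],
                 class = "polIV_te", bias = cfg$biallelic_bias),
      data.frame(mirna[c("feature_id", "chrom", "start", "end")],
                 class = "mirna", bias = cfg$biallelic_bias),
      data.frame(isr_m[c("feature_id", "chrom", "start", "end")],
                 class = "isr_mat", bias = cfg$mat_isr_bias),
      data.frame(isr_p[c("feature_id", "chrom", "start", "end")],
                 class = "isr_pat", bias = cfg$pat_isr_bias))
    names(loci)[1] <- "locus_id"
    w <- stats::rexp(nrow(loci)) + 0.5
    loci$mean_reads <- w / sum(w) * cfg$srna_reads *
      (1 - cfg$background_frac)
    rownames(loci) <- NULL

    # per-gene mRNA effects
    ng <- nrow(genes)
    need <- cfg$n_antagonistic + cfg$n_mat_effect + cfg$n_pat_effect +
      cfg$n_both_parent
    if (need + cfg$n_meg + cfg$n_peg > ng)
      stopf("gene effect panels exceed n_genes")
    panel_lab <- rep("none", ng)
    idx <- sample(ng)  # shuffle, then carve consecutive panels
    take <- function(n) {
      out <- idx[seq_len(n)]
      idx <<- idx[-seq_len(n)]
      out
    }
    i_ant <- take(cfg$n_antagonistic)
    i_mat <- take(cfg$n_mat_effect)
    i_pat <- take(cfg$n_pat_effect)
    i_both <- take(cfg$n_both_parent)
    panel_lab[i_ant] <- "antagonistic"
    panel_lab[i_mat] <- "mat_effect"
    panel_lab[i_pat] <- "pat_effect"
    panel_lab[i_both] <- "both_parent"
    rbeta_ <- function(n) sample(c(-1, 1), n, replace = TRUE) *
      stats::runif(n, cfg$beta_range[1], cfg$beta_range[2])
    beta_mat <- numeric(ng); beta_pat <- numeric(ng)
    beta_mat[i_ant] <- rbeta_(length(i_ant))
    beta_pat[i_ant] <- -cfg$antagonism_ratio * beta_mat[i_ant]
    beta_mat[i_mat] <- rbeta_(length(i_mat))
    beta_pat[i_pat] <- rbeta_(length(i_pat))
    beta_mat[i_both] <- rbeta_(length(i_both))
    beta_pat[i_both] <- sign(beta_mat[i_both]) *
      stats::runif(length(i_both), cfg$beta_range[1], cfg$beta_range[2])
    imprint <- rep("none", ng)
    i_meg <- take(cfg$n_meg); i_peg <- take(cfg$n_peg)
    imprint[i_meg] <- "MEG"; imprint[i_peg] <- "PEG"
    p_maternal <- rep(2 / 3, ng)
    p_maternal[i_meg] <- 0.95
    p_maternal[i_peg] <- 0.05
    gene_truth <- data.frame(
      gene_id = genes$feature_id, chrom = genes$chrom,
      start = genes$start, end = genes$end, strand = genes$strand,
      beta0 = stats::runif(ng, cfg$mrna_baseline_log2[1],
                           cfg$mrna_baseline_log2[2]),
      beta_mat = beta_mat, beta_pat = beta_pat, panel = panel_lab,
      imprint = imprint, p_maternal = p_maternal,
      antagonistic = beta_mat * beta_pat < 0)

    cytosines <- build_cytosine_truth(genome, cfg, tes, isr_m, isr_p)

    truth <- list(loci = loci, genes = gene_truth, cytosines = cytosines,
                  dosage = 2 / 3)
    structure(list(genome = genome,
                   maternal_genome = build_pseudogenome(genome, snps),
                   snps = snps, features = features, truth = truth,
                   config = cfg),
              class = "endosperm_sim")
  })
}

# per-cytosine methylation regime: background, RdDM target kind, chloroplast
build_cytosine_truth <- function(genome, cfg, tes, isr_m, isr_p) {
  per_ctg <- lapply(names(genome), function(ctg) {
    s <- as.character(genome[[ctg]])
    plus <- as.integer(gregexpr("C", s, fixed = TRUE)[[1]])
    minus <- as.integer(gregexpr("G", s, fixed = TRUE)[[1]])
    plus <- plus[plus > 0]; minus <- minus[minus > 0]
    data.frame(chrom = ctg, pos = c(plus, minus),
               strand = rep(c("+", "-"), c(length(plus), length(minus))))
  })
  cyt <- do.call(rbind, per_ctg)
  cyt <- cyt[order(cyt$chrom, cyt$pos), ]
  rownames(cyt) <- NULL
  calls0 <- data.frame(cyt, context = NA_character_, n_meth = 0L,
                       n_total = 1L, allele = "ambiguous")
  ctx <- pileup_contexts(calls0, genome)
  cyt <- ctx[c("chrom", "pos", "strand", "context")]
  region <- rep("background", nrow(cyt))
  gr <- GenomicRanges::GRanges(cyt$chrom, IRanges::IRanges(cyt$pos,
                                                           cyt$pos))
  mark <- function(d, lab) {
    if (is.null(d) || nrow(d) == 0) return()
    g <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end))
    region[GenomicRanges::countOverlaps(gr, g) > 0] <<- lab
  }
  mark(tes, "te_target")
  mark(isr_m, "mat_target")
  mark(isr_p, "pat_target")
  region[cyt$chrom == cfg$chloroplast_name] <- "chloroplast"
  cyt$region <- region
  cyt
}

# per-genotype activity of the maternal/paternal component of an sRNA locus
locus_component_active <- function(class, genotype) {
  mother_wt <- genotype %in% c("WT", "pat_het")
  father_wt <- genotype %in% c("WT", "mat_het")
  polIV <- genotype != "null"
  mat <- switch(class,
                mirna = TRUE,
                isr_mat = mother_wt,
                isr_pat = polIV,
                polIV_gene = , polIV_te = polIV)
  pat <- switch(class,
                mirna = TRUE,
                isr_mat = polIV,
                isr_pat = father_wt,
                polIV_gene = , polIV_te = polIV)
  c(maternal = mat, paternal = pat)
}

#' Simulate one sRNA library
#'
#' Per-locus read counts are negative-binomial around the locus's
#' configured mean, split into maternal and paternal components by the
#' locus's allelic bias. Pol IV-dependent loci emit only background in the
#' null; maternal-memory ISR loci emit maternal-allele reads only when the
#' mother is wild type (so they are silenced in `mat_het` and `null` but
#' untouched in `pat_het`); paternal-memory loci are symmetric; miRNA loci
#' ignore genotype. Read sizes follow the configured distribution (24 nt
#' predominant; miRNA loci use their own, 21-nt-predominant distribution).
#' Reads are emitted pre-aligned, error-free, with the emitting allele
#' recorded in `true_allele` and the emitting locus (or `"background"`)
#' in `source`.
#'
#' @param sim an `endosperm_sim` (see [simulate_genome_and_snps()]).
#' @param genotype one of `WT`, `mat_het`, `pat_het`, `null`.
#' @param replicate replicate index.
#' @return An `aligned_reads` data frame with an extra `true_allele`
#'   column.
#' @export
simulate_srna_reads <- function(sim, genotype, replicate = 1) {
  if (!genotype %in% GENOTYPES)
    stopf("unknown genotype label: %s", genotype)
  cfg <- sim$config
  loci <- sim$truth$loci
  with_stream(stream_seed(cfg$seed, "srna", genotype, replicate), {
    recs <- vector("list", nrow(loci) + 1)
    for (i in seq_len(nrow(loci))) {
      act <- locus_component_active(loci$class[i], genotype)
      mu_m <- loci$mean_reads[i] * loci$bias[i] * act["maternal"]
      mu_p <- loci$mean_reads[i] * (1 - loci$bias[i]) * act["paternal"]
      n_m <- if (mu_m > 0)
        stats::rnbinom(1, mu = mu_m, size = 1 / cfg$srna_dispersion) else 0L
      n_p <- if (mu_p > 0)
        stats::rnbinom(1, mu = mu_p, size = 1 / cfg$srna_dispersion) else 0L
      n <- n_m + n_p
      if (n == 0) next
      probs <- if (loci$class[i] == "mirna") cfg$mirna_size_probs
               else cfg$srna_size_probs
      len <- as.integer(sample(names(probs), n, replace = TRUE,
                               prob = probs))
      start <- loci$start[i] +
        floor(stats::runif(n) * pmax(loci$end[i] - loci$start[i] + 1 - len,
                                     1))
      recs[[i]] <- data.frame(
        chrom = loci$chrom[i], start = as.integer(start), length = len,
        strand = sample(c("+", "-"), n, replace = TRUE),
        true_allele = rep(c("maternal", "paternal"), c(n_m, n_p)),
        source = loci$locus_id[i])
    }
    # Pol IV-independent background: uniform over the nuclear genome,
    # alleles at genome dosage
    n_bg <- stats::rpois(1, cfg$srna_reads * cfg$background_frac)
    if (n_bg > 0) {
      ctgs <- setdiff(names(sim$genome), cfg$chloroplast_name)
      lens <- contig_lengths(sim$genome)[ctgs]
      ctg <- sample(ctgs, n_bg, replace = TRUE, prob = lens)
      len <- as.integer(sample(names(cfg$srna_size_probs), n_bg,
                               replace = TRUE, prob = cfg$srna_size_probs))
      start <- 1L + floor(stats::runif(n_bg) * (lens[ctg] - len))
      recs[[nrow(loci) + 1]] <- data.frame(
        chrom = ctg, start = as.integer(start), length = len,
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        true_allele = ifelse(stats::runif(n_bg) < sim$truth$dosage,
                             "maternal", "paternal"),
        source = "background")
    }
    reads <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
    if (is.null(reads)) return(aligned_reads_empty())
    rownames(reads) <- NULL
    # sequence from the emitting parental genome (error-free placement)
    reads$sequence <- NA_character_
    for (ctg in unique(reads$chrom)) {
      for (al in c("maternal", "paternal")) {
        sel <- reads$chrom == ctg & reads$true_allele == al
        if (!any(sel)) next
        src <- if (al == "maternal") sim$maternal_genome else sim$genome
        reads$sequence[sel] <- substring(as.character(src[[ctg]]),
                                         reads$start[sel],
                                         reads$start[sel] +
                                           reads$length[sel] - 1L)
      }
    }
    minus <- reads$strand == "-"
    if (any(minus)) reads$sequence[minus] <- revcomp(reads$sequence[minus])
    reads$read_id <- sprintf("%s_r%d_%07d", genotype, replicate,
                             seq_len(nrow(reads)))
    reads$n_hits <- 1L
    out <- reads[c("read_id", "chrom", "start", "strand", "sequence",
                   "length", "n_hits", "true_allele", "source")]
    structure(out, class = c("aligned_reads", "data.frame"), n_skipped = 0L)
  })
}

#' Simulate genomic DNA reads at the endosperm dosage
#'
#' Emits error-free DNA reads uniform over the nuclear genome, each drawn
#' from the maternal genome with probability 2/3 and the paternal genome
#' otherwise (the triploid endosperm dosage), for dosage-recovery checks of
#' the allele-assignment machinery.
#'
#' @param sim an `endosperm_sim`.
#' @param genotype genotype label (DNA dosage is genotype-independent;
#'   recorded for stream derivation only).
#' @param replicate replicate index.
#' @param n_reads number of reads.
#' @param read_len read length in nt.
#' @return An `aligned_reads` data frame with a `true_allele` column.
#' @export
simulate_dna_reads <- function(sim, genotype = "WT", replicate = 1,
                               n_reads = 50000, read_len = 60) {
  cfg <- sim$config
  with_stream(stream_seed(cfg$seed, "dna", genotype, replicate), {
    ctgs <- setdiff(names(sim$genome), cfg$chloroplast_name)
    lens <- contig_lengths(sim$genome)[ctgs]
    ctg <- sample(ctgs, n_reads, replace = TRUE, prob = lens)
    start <- 1L + floor(stats::runif(n_reads) * (lens[ctg] - read_len))
    allele <- ifelse(stats::runif(n_reads) < sim$truth$dosage,
                     "maternal", "paternal")
    reads <- data.frame(read_id = sprintf("dna_%07d", seq_len(n_reads)),
                        chrom = ctg, start = as.integer(start),
                        strand = sample(c("+", "-"), n_reads,
                                        replace = TRUE),
                        sequence = NA_character_,
                        length = as.integer(read_len), n_hits = 1L,
                        true_allele = allele)
    for (c1 in unique(reads$chrom)) {
      for (al in c("maternal", "paternal")) {
        sel <- reads$chrom == c1 & reads$true_allele == al
        if (!any(sel)) next
        src <- if (al == "maternal") sim$maternal_genome else sim$genome
        reads$sequence[sel] <- substring(as.character(src[[c1]]),
                                         reads$start[sel],
                                         reads$start[sel] + read_len - 1L)
      }
    }
    minus <- reads$strand == "-"
    if (any(minus)) reads$sequence[minus] <- revcomp(reads$sequence[minus])
    rownames(reads) <- NULL
    structure(reads, class = c("aligned_reads", "data.frame"),
              n_skipped = 0L)
  })
}

#' Simulate mRNA counts for a set of genotypes
#'
#' Per gene g the log2 mean is
#' `beta0 + beta_mat * I(mother mutant) + beta_pat * I(father mutant)`
#' (mother mutant in `mat_het` and `null`; father mutant in `pat_het` and
#' `null`), so the null genotype obeys exact additivity of the two
#' parental effects in the noiseless means. Counts are NB around the mean;
#' the allele-informative subset of each count is split beta-binomially
#' around 2/3 maternal for non-imprinted genes and near 1 (MEG) or 0 (PEG)
#' for imprinted ones.
#'
#' @param sim an `endosperm_sim`.
#' @param genotypes genotypes to simulate (default all four).
#' @param n_reps replicates per genotype (at least 2 for downstream
#'   testing).
#' @return List of three `count_set`s: `total`, `maternal`, `paternal`.
#' @export
simulate_mrna_counts <- function(sim, genotypes = GENOTYPES, n_reps = 3) {
  cfg <- sim$config
  g <- sim$truth$genes
  cols <- list(); meta <- list(); mat <- list(); pat <- list()
  for (gt in genotypes) {
    mother_mut <- gt %in% c("mat_het", "null")
    father_mut <- gt %in% c("pat_het", "null")
    mu <- 2^(g$beta0 + g$beta_mat * mother_mut + g$beta_pat * father_mut)
    for (r in seq_len(n_reps)) {
      draw <- with_stream(stream_seed(cfg$seed, "mrna", gt, r), {
        total <- stats::rnbinom(nrow(g), mu = mu,
                                size = 1 / cfg$mrna_dispersion)
        info <- stats::rbinom(nrow(g), total, cfg$mrna_info_frac)
        k <- cfg$allelic_concentration
        p <- stats::rbeta(nrow(g), g$p_maternal * k,
                          (1 - g$p_maternal) * k)
        m <- stats::rbinom(nrow(g), info, p)
        list(total = total, m = m, info = info)
      })
      id <- sprintf("%s_r%d", gt, r)
      cols[[id]] <- draw$total
      mat[[id]] <- draw$m
      pat[[id]] <- draw$info - draw$m
      meta[[id]] <- data.frame(sample_id = id, genotype = gt,
                               replicate = r)
    }
  }
  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL
  feats <- data.frame(feature_id = g$gene_id, feature_class = "gene",
                      chrom = g$chrom, start = g$start, end = g$end)
  list(total = count_set(do.call(cbind, cols), feats, samples),
       maternal = count_set(do.call(cbind, mat), feats, samples),
       paternal = count_set(do.call(cbind, pat), feats, samples))
}

#' Simulate one bisulfite methylome
#'
#' Per cytosine, allele-resolved read depth follows the 2 maternal : 1
#' paternal genome dosage (Poisson around 2/3 and 1/3 of `depth`). The
#' methylated count is binomial in the true, context- and region-specific
#' methylation level: CHH at RdDM targets is high when the controlling
#' parent's Pol IV was active and collapses to `chh_lost` when it was not
#' (maternal-memory targets respond to the mother's genotype,
#' paternal-memory targets to the father's, biallelic TE targets only to
#' the null); the chloroplast is truly unmethylated. A truly unmethylated
#' cytosine still reads as methylated with probability
#' `1 - conversion_rate` (incomplete bisulfite conversion). A configurable
#' fraction of reads is allele-assignable; the rest are ambiguous.
#'
#' @param sim an `endosperm_sim`.
#' @param genotype genotype label.
#' @param replicate replicate index.
#' @return A methylation-call data frame (one row per cytosine x allele
#'   class with nonzero depth) suitable for [methyl_join()] etc.
#' @export
simulate_methylome <- function(sim, genotype, replicate = 1) {
  if (!genotype %in% GENOTYPES)
    stopf("unknown genotype label: %s", genotype)
  cfg <- sim$config
  cyt <- sim$truth$cytosines
  mother_mut <- genotype %in% c("mat_het", "null")
  father_mut <- genotype %in% c("pat_het", "null")
  p <- unname(cfg$meth_background[cyt$context])
  is_chh <- cyt$context == "CHH"
  rddm_on <- (cyt$region == "te_target" & genotype != "null") |
    (cyt$region == "mat_target" & !mother_mut) |
    (cyt$region == "pat_target" & !father_mut)
  rddm_off <- cyt$region %in% c("te_target", "mat_target", "pat_target") &
    !rddm_on
  p[is_chh & rddm_on] <- cfg$chh_rddm
  p[is_chh & rddm_off] <- cfg$chh_lost
  p[cyt$region == "chloroplast"] <- 0
  p_obs <- p + (1 - p) * (1 - cfg$conversion_rate)
  n <- nrow(cyt)
  with_stream(stream_seed(cfg$seed, "meth", genotype, replicate), {
    d_mat <- stats::rpois(n, cfg$depth * 2 / 3)
    d_pat <- stats::rpois(n, cfg$depth * 1 / 3)
    a_mat <- stats::rbinom(n, d_mat, cfg$meth_assignable_frac)
    a_pat <- stats::rbinom(n, d_pat, cfg$meth_assignable_frac)
    d_amb <- (d_mat - a_mat) + (d_pat - a_pat)
    piece <- function(total, allele) {
      keep <- total > 0
      data.frame(chrom = cyt$chrom[keep], pos = cyt$pos[keep],
                 strand = cyt$strand[keep], context = cyt$context[keep],
                 n_meth = stats::rbinom(sum(keep), total[keep],
                                        p_obs[keep]),
                 n_total = total[keep], allele = allele)
    }
    out <- rbind(piece(a_mat, "maternal"), piece(a_pat, "paternal"),
                 piece(d_amb, "ambiguous"))
    out <- out[order(out$chrom, out$pos, out$allele), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-nucleotide 5'-end tracks
#'
#' Every gene gets a transcription-start-site spike at its strand-aware 5'
#' end, Poisson around `nanopare_tss_scale` times the gene's mRNA mean in
#' that genotype; the designated cleavage-target genes additionally carry
#' an internal (mid-gene) spike that is present only while the associated
#' sRNA locus is active (absent in the null); a fixed panel of noise sites
#' adds a uniform floor. The site universe is identical across genotypes
#' so tracks are directly comparable.
#'
#' @param sim an `endosperm_sim`.
#' @param genotypes genotypes to simulate.
#' @param n_reps replicates per genotype.
#' @return A `count_set` whose features are nucleotide sites (`chrom`,
#'   `pos`, `strand`, and the generator's `site_type` of
#'   tss/cleavage/noise with `gene_id`).
#' @export
simulate_nanopare <- function(sim, genotypes = c("WT", "null"),
                              n_reps = 3) {
  cfg <- sim$config
  g <- sim$truth$genes
  tss <- ifelse(g$strand == "-", g$end, g$start)
  cleave_ids <- with_stream(stream_seed(cfg$seed, "nanopare", "sites"), {
    srna_genes <- sim$truth$loci$locus_id[sim$truth$loci$class ==
                                            "polIV_gene"]
    sample(srna_genes, min(cfg$n_cleavage_genes, length(srna_genes)))
  })
  ci <- match(cleave_ids, g$gene_id)
  cleave_pos <- (g$start[ci] + g$end[ci]) %/% 2L
  noise <- with_stream(stream_seed(cfg$seed, "nanopare", "noise"), {
    ctgs <- setdiff(names(sim$genome), cfg$chloroplast_name)
    lens <- contig_lengths(sim$genome)[ctgs]
    ctg <- sample(ctgs, cfg$nanopare_noise_sites, replace = TRUE,
                  prob = lens)
    data.frame(chrom = ctg,
               pos = 1L + floor(stats::runif(cfg$nanopare_noise_sites) *
                                  lens[ctg]),
               strand = "+", site_type = "noise", gene_id = NA_character_)
  })
  feats <- rbind(
    data.frame(chrom = g$chrom, pos = tss, strand = g$strand,
               site_type = "tss", gene_id = g$gene_id),
    data.frame(chrom = g$chrom[ci], pos = cleave_pos,
               strand = g$strand[ci], site_type = "cleavage",
               gene_id = g$gene_id[ci]),
    noise)
  feats$feature_id <- sprintf("site_%s:%d:%s", feats$chrom, feats$pos,
                              feats$site_type)
  feats$feature_class <- "site"
  cols <- list(); meta <- list()
  for (gt in genotypes) {
    mother_mut <- gt %in% c("mat_het", "null")
    father_mut <- gt %in% c("pat_het", "null")
    mu_gene <- 2^(g$beta0 + g$beta_mat * mother_mut +
                    g$beta_pat * father_mut)
    mu <- numeric(nrow(feats))
    mu[feats$site_type == "tss"] <- cfg$nanopare_tss_scale * mu_gene
    mu[feats$site_type == "cleavage"] <-
      if (gt == "null") 0 else cfg$nanopare_cleavage_mean
    mu[feats$site_type == "noise"] <- cfg$nanopare_noise_mean
    for (r in seq_len(n_reps)) {
      id <- sprintf("%s_r%d", gt, r)
      cols[[id]] <- with_stream(stream_seed(cfg$seed, "nanopare", gt, r),
                                stats::rpois(nrow(feats), mu))
      meta[[id]] <- data.frame(sample_id = id, genotype = gt,
                               replicate = r)
    }
  }
  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL
  count_set(do.call(cbind, cols), feats, samples)
}
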