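# small simulated dataset shared across test files (built once per run)
small_config <- function(seed = 11, ...) {
  sim_config(seed = seed,
             n_contigs = 2, contig_bp = 50000L, chloroplast_bp = 20000L,
             n_genes = 60L, n_tes = 30L, n_mirna = 5L,
             n_isr_mat = 5L, n_isr_pat = 5L,
             srna_reads = 20000L,
             n_antagonistic = 10L, n_mat_effect = 10L, n_pat_effect = 5L,
             n_both_parent = 5L, n_meg = 6L, n_peg = 4L,
             n_cleavage_genes = 5L, nanopare_noise_sites = 100L,
             ...)
}

.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$sim)) .sim_cache$sim <- simulate_genome_and_snps(small_config())
  .sim_cache$sim
}

# hand-built aligned_reads for unit tests
make_reads <- function(chrom, start, strand = "+", sequence, n_hits = 1L) {
  n <- max(length(chrom), length(start), length(sequence))
  df <- data.frame(read_id = sprintf("r%d", seq_len(n)),
                   chrom = rep_len(chrom, n), start = rep_len(start, n),
                   strand = rep_len(strand, n),
                   sequence = rep_len(sequence, n),
                   n_hits = rep_len(as.integer(n_hits), n))
  df$length <- nchar(df$sequence)
  structure(df[c("read_id", "chrom", "start", "strand", "sequence",
                 "length", "n_hits")],
            class = c("aligned_reads", "data.frame"), n_skipped = 0L)
}

make_granges <- function(chrom, start, end, id = NULL, class = "gene",
                         strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand,
                         feature_id = id %||% sprintf("f%d",
                                                      seq_along(start)),
                         feature_class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles ----

# exhaustive hypergeometric upper tail by enumerating all draws
hyper_enum <- function(k, n1, n2, N) {
  universe <- seq_len(N)
  set1 <- seq_len(n1)
  draws <- utils::combn(N, n2)
  overlaps <- apply(draws, 2, function(d) length(intersect(d, set1)))
  mean(overlaps >= k)
}

# exact NB likelihood-ratio statistic for one feature, two groups.
# The ML mean of an NB sample is its sample mean, so the likelihood is
# profiled over the dispersion alone (1-D optimize).
nb_lr_stat <- function(ya, yb) {
  nll <- function(la, mu_a, mu_b) {
    -sum(stats::dnbinom(ya, mu = mu_a, size = exp(-la), log = TRUE)) -
      sum(stats::dnbinom(yb, mu = mu_b, size = exp(-la), log = TRUE))
  }
  prof <- function(mu_a, mu_b)
    stats::optimize(nll, c(-20, 10), mu_a = mu_a, mu_b = mu_b)$objective
  mu0 <- max(mean(c(ya, yb)), 1e-8)
  ll_null <- -prof(mu0, mu0)
  ll_alt <- -prof(max(mean(ya), 1e-8), max(mean(yb), 1e-8))
  list(lr = max(2 * (ll_alt - ll_null), 0), mu0 = mu0,
       alpha0 = {
     o <- stats::optimize(nll, c(-20, 10), mu_a = mu0, mu_b = mu0)
     exp(o$minimum)
   })
}

# exact NB likelihood-ratio test with finite-sample (parametric bootstrap)
# calibration: the null distribution of the LR statistic is obtained by
# simulating from the fitted null model
nb_lr_test <- function(ya, yb, n_boot = 199) {
  obs <- nb_lr_stat(ya, yb)
  na <- length(ya); nb <- length(yb)
  lr_boot <- replicate(n_boot, {
    y <- stats::rnbinom(na + nb, mu = obs$mu0, size = 1 / obs$alpha0)
    nb_lr_stat(y[seq_len(na)], y[na + seq_len(nb)])$lr
  })
  (1 + sum(lr_boot >= obs$lr)) / (1 + n_boot)
}

# brute-force all-pairs minimum edge-to-edge distance (0 when overlapping)
pairwise_min_dist <- function(genes, regions) {
  gd <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                   start = GenomicRanges::start(genes),
                   end = GenomicRanges::end(genes))
  rd <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions),
                   end = GenomicRanges::end(regions))
  vapply(seq_len(nrow(gd)), function(i) {
    same <- rd$chrom == gd$chrom[i]
    if (!any(same)) return(NA_real_)
    d <- pmax(0, pmax(rd$start[same] - gd$end[i],
                      gd$start[i] - rd$end[same]) - 1)
    # adjacent intervals ([1,5],[6,9]) have gap 0 under the edge-to-edge
    # convention used by IRanges::distance
    min(d)
  }, 0)
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

default_sim <- function() {
  if (is.null(.sim_cache$default))
    .sim_cache$default <- simulate_genome_and_snps(sim_config(seed = 2024))
  .sim_cache$default
}
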