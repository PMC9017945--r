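#' Classify allelic bias of features
#'
#' Features with more than `upper` percent of allele-informative reads from
#' maternal alleles are maternally biased, below `lower` percent paternally
#' biased, and within `[lower, upper]` (inclusive: "between 20% and 80%")
#' biallelic. Features with fewer informative reads than `floor` are
#' untestable.
#'
#' @param allelic_counts output of [allelic_feature_counts()].
#' @param floor minimum informative reads (default 10).
#' @param lower,upper biallelic band in percent maternal (default 20/80).
#' @return Data frame: `feature_id`, `percent_maternal`, `class`.
#' @export
classify_bias <- function(allelic_counts, floor = 10, lower = 20,
                          upper = 80) {
  inf <- allelic_counts$maternal + allelic_counts$paternal
  pm <- allelic_counts$percent_maternal
  cls <- rep("biallelic", nrow(allelic_counts))
  cls[!is.na(pm) & pm > upper] <- "maternally_biased"
  cls[!is.na(pm) & pm < lower] <- "paternally_biased"
  cls[inf < floor] <- "untestable"
  data.frame(feature_id = allelic_counts$feature_id,
             percent_maternal = pm, class = cls)
}

#' Summarize window counts over imprinted sRNA regions
#'
#' For each ISR, finds the (300/100-dialect) windows overlapping it, merges
#' the overlapping windows into one set per region, and reports the median
#' normalized count per sample column (midpoint rule for even counts).
#' When window-level differential results are supplied, the number of
#' significantly changed windows per region is reported alongside.
#'
#' @param window_cs a `count_set` of window counts whose features carry
#'   `chrom`, `start`, `end`.
#' @param isr a `GRanges` of ISR intervals with `feature_id`.
#' @param size_factors optional per-sample factors; counts are divided by
#'   them before the median.
#' @param results optional classified differential results keyed by window
#'   `feature_id`.
#' @return Data frame with one row per ISR: `isr_id`, `n_windows`, one
#'   `median_<sample>` column per sample, and (when `results` given)
#'   `n_sig` windows called up or down. ISRs with no windows get `NA`
#'   medians.
#' @export
isr_summary <- function(window_cs, isr, size_factors = NULL,
                        results = NULL) {
  counts <- window_cs$counts
  if (!is.null(size_factors)) counts <- sweep(counts, 2, size_factors, "/")
  wgr <- GenomicRanges::GRanges(window_cs$features$chrom,
                                IRanges::IRanges(window_cs$features$start,
                                                 window_cs$features$end))
  hits <- GenomicRanges::findOverlaps(wgr, isr)
  out <- data.frame(isr_id = S4Vectors::mcols(isr)$feature_id,
                    n_windows = 0L)
  med <- matrix(NA_real_, nrow = length(isr), ncol = ncol(counts),
                dimnames = list(NULL,
                                paste0("median_", colnames(counts))))
  n_sig <- rep(NA_integer_, length(isr))
  by_isr <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  for (k in names(by_isr)) {
    i <- as.integer(k)
    wi <- by_isr[[k]]
    out$n_windows[i] <- length(wi)
    med[i, ] <- apply(counts[wi, , drop = FALSE], 2, stats::median)
    if (!is.null(results)) {
      calls <- results$call[match(window_cs$features$feature_id[wi],
                                  results$feature_id)]
      n_sig[i] <- sum(calls %in% c("up", "down"), na.rm = TRUE)
    }
  }
  out <- cbind(out, as.data.frame(med))
  if (!is.null(results)) out$n_sig <- n_sig
  out
}

#' Upper-tail hypergeometric enrichment
#'
#' Probability of observing at least `k_overlap` common elements between two
#' sets of the given sizes drawn from a shared universe, P(X >= k) under
#' the hypergeometric law (computed in log space via [stats::phyper()], so
#' it is stable for large arguments).
#'
#' @param k_overlap observed overlap.
#' @param set1_size,set2_size set sizes.
#' @param universe_size universe size.
#' @return The upper-tail probability.
#' @export
hypergeom_enrichment <- function(k_overlap, set1_size, set2_size,
                                 universe_size) {
  if (set1_size > universe_size || set2_size > universe_size ||
      k_overlap > min(set1_size, set2_size) || k_overlap < 0)
    stopf("inconsistent sizes: k=%d, sets %d/%d, universe %d",
          k_overlap, set1_size, set2_size, universe_size)
  if (k_overlap == 0) return(1)
  exp(stats::phyper(k_overlap - 1, set1_size, universe_size - set1_size,
                    set2_size, lower.tail = FALSE, log.p = TRUE))
}
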