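#' Build a SNP-substitution pseudogenome
#'
#' Substitutes the alternate base at every SNP position, producing the other
#' parent's genome in the same coordinate frame (a SNP-only pseudogenome, so
#' liftover between the two frames is the identity map).
#'
#' @param reference a genome ([Biostrings::DNAStringSet]).
#' @param snps a `snp_table`; every `ref` base must match the reference.
#' @return A `DNAStringSet` differing from `reference` exactly at SNP
#'   positions.
#' @export
build_pseudogenome <- function(reference, snps) {
  out <- reference
  for (ctg in unique(snps$chrom)) {
    if (!ctg %in% names(reference))
      stopf("SNP contig %s absent from reference", ctg)
    idx <- which(snps$chrom == ctg)
    seq_chr <- as.character(reference[[ctg]])
    have <- substring(seq_chr, snps$pos[idx], snps$pos[idx])
    bad <- which(have != snps$ref[idx])
    if (length(bad) > 0)
      stopf("ref_base mismatch at %s:%d (reference has %s, SNP says %s)",
            ctg, snps$pos[idx][bad[1]], have[bad[1]], snps$ref[idx][bad[1]])
    out[[ctg]] <- Biostrings::replaceLetterAt(
      reference[[ctg]], snps$pos[idx],
      paste(snps$alt[idx], collapse = ""))
  }
  out
}

#' Assign reads to parental alleles via SNP overlap
#'
#' For each read, collects the SNPs its alignment span overlaps and compares
#' the read base at each to the two parental bases. All informative positions
#' agreeing on one parent gives that parent; zero overlapped SNPs, a
#' non-parental base, or conflicting votes give `ambiguous` (conservative
#' exclusion rather than an error, to avoid allele-bias artifacts).
#'
#' @param reads an `aligned_reads` data frame.
#' @param snps a `snp_table`.
#' @param genome the reference genome (used for bounds checking).
#' @return Character vector (`maternal`/`paternal`/`ambiguous`), one per read.
#' @export
assign_allele <- function(reads, snps, genome) {
  lens <- contig_lengths(genome)
  if (nrow(reads) == 0) return(character(0))
  if (any(reads$start + reads$length - 1L > lens[reads$chrom]))
    stopf("read extends past contig end (malformed input)")
  out <- rep("ambiguous", nrow(reads))
  if (nrow(snps) == 0) return(out)
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(reads_granges(reads), snp_gr)
  if (length(hits) == 0) return(out)
  ri <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  # base the read reports at the SNP position, in reference orientation
  offset <- snps$pos[si] - reads$start[ri] + 1L
  plus <- reads$strand[ri] == "+"
  base <- character(length(ri))
  base[plus] <- substring(reads$sequence[ri][plus], offset[plus],
                          offset[plus])
  if (any(!plus)) {
    ro <- reads$length[ri][!plus] - offset[!plus] + 1L
    raw <- substring(reads$sequence[ri][!plus], ro, ro)
    base[!plus] <- chartr("ACGTN", "TGCAN", raw)
  }
  mat_base <- ifelse(snps$parent_of_ref[si] == "maternal", snps$ref[si],
                     snps$alt[si])
  pat_base <- ifelse(snps$parent_of_ref[si] == "maternal", snps$alt[si],
                     snps$ref[si])
  vote <- ifelse(base == mat_base, "maternal",
                 ifelse(base == pat_base, "paternal", "neither"))
  n_mat <- tapply(vote == "maternal", ri, sum)
  n_pat <- tapply(vote == "paternal", ri, sum)
  n_bad <- tapply(vote == "neither", ri, sum)
  idx <- as.integer(names(n_mat))
  call <- rep("ambiguous", length(idx))
  call[n_mat > 0 & n_pat == 0 & n_bad == 0] <- "maternal"
  call[n_pat > 0 & n_mat == 0 & n_bad == 0] <- "paternal"
  out[idx] <- call
  out
}

#' Tally allele-assigned reads per feature
#'
#' A read counts toward the single feature containing its 5' start (ties go
#' to the earlier coordinate-sorted feature) so totals are conserved across
#' overlapping annotations. Multimapped reads (`n_hits > 1`) are excluded
#' from the maternal/paternal tallies (allele inference from multimapped
#' placements is unreliable) and counted as ambiguous.
#'
#' @param reads an `aligned_reads` data frame.
#' @param features a `GRanges` with `feature_id` and `feature_class`.
#' @param snps a `snp_table`.
#' @param genome the reference genome.
#' @param floor minimum informative (maternal + paternal) reads for a
#'   feature to be flagged testable.
#' @return A `data.frame` of class `allelic_counts`: `feature_id`,
#'   `feature_class`, `maternal`, `paternal`, `ambiguous`,
#'   `percent_maternal` (`NA` when no informative reads), `testable`.
#' @export
allelic_feature_counts <- function(reads, features, snps, genome,
                                   floor = 10) {
  allele <- assign_allele(reads, snps, genome)
  allele[reads$n_hits > 1] <- "ambiguous"
  ord <- order(as.character(GenomicRanges::seqnames(features)),
               GenomicRanges::start(features))
  feats <- features[ord]
  fp <- five_prime(reads)
  pos_gr <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(fp, fp))
  fidx <- GenomicRanges::findOverlaps(pos_gr, feats, select = "first")
  res <- data.frame(feature_id = S4Vectors::mcols(feats)$feature_id,
                    feature_class = S4Vectors::mcols(feats)$feature_class,
                    maternal = 0, paternal = 0, ambiguous = 0)
  if (nrow(reads) > 0) {
    keep <- !is.na(fidx)
    tab <- table(factor(fidx[keep], levels = seq_along(feats)),
                 factor(allele[keep], levels = ALLELES))
    res$maternal <- as.numeric(tab[, "maternal"])
    res$paternal <- as.numeric(tab[, "paternal"])
    res$ambiguous <- as.numeric(tab[, "ambiguous"])
  }
  inf <- res$maternal + res$paternal
  res$percent_maternal <- ifelse(inf > 0, 100 * res$maternal / inf, NA_real_)
  res$testable <- inf >= floor
  structure(res, class = c("allelic_counts", "data.frame"))
}
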