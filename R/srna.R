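#' Collapse PCR duplicates
#'
#' Keeps exactly one representative per distinct sequence string (library
#' adapters carry random terminal bases, so true duplicates are identical
#' over the full sequence while independent molecules differ).
#'
#' @param reads an `aligned_reads` data frame.
#' @return Deduplicated reads, with attribute `n_removed`.
#' @export
deduplicate <- function(reads) {
  keep <- !duplicated(reads$sequence)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(reads), n_removed = sum(!keep))
}

#' Bin reads by length
#'
#' @param reads an `aligned_reads` data frame (deduplicated).
#' @param min,max inclusive size range; reads outside it fall in no bin.
#' @param denominator `"all"` computes size fractions over all reads (the
#'   convention for size-profile plots), `"in_range"` over binned reads only.
#' @return A list with `bins` (a named list of read subsets) and `fractions`
#'   (data frame of `size`, `n`, `fraction`).
#' @export
bin_by_size <- function(reads, min = 21, max = 24,
                        denominator = c("all", "in_range")) {
  denominator <- match.arg(denominator)
  if (min > max) stopf("min (%d) > max (%d)", min, max)
  sizes <- min:max
  bins <- lapply(sizes, function(s) {
    out <- reads[reads$length == s, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(bins) <- as.character(sizes)
  n <- vapply(bins, nrow, integer(1))
  denom <- if (denominator == "all") nrow(reads) else sum(n)
  list(bins = bins,
       fractions = data.frame(size = sizes, n = as.integer(n),
                              fraction = if (denom > 0) n / denom
                                         else rep(NA_real_, length(n))))
}

# sliding windows tiling each contig; only full-width windows are produced
tile_windows <- function(genome, window_bp = 300, step_bp = 100) {
  if (window_bp <= 0 || step_bp <= 0)
    stopf("window_bp and step_bp must be positive")
  lens <- contig_lengths(genome)
  grl <- lapply(names(lens), function(ctg) {
    if (lens[ctg] < window_bp) return(GenomicRanges::GRanges())
    starts <- seq.int(1L, lens[ctg] - window_bp + 1L, by = step_bp)
    GenomicRanges::GRanges(ctg, IRanges::IRanges(starts,
                                                 starts + window_bp - 1L))
  })
  gr <- suppressWarnings(do.call(c, grl))
  S4Vectors::mcols(gr)$feature_id <- sprintf(
    "%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
    GenomicRanges::start(gr), GenomicRanges::end(gr))
  S4Vectors::mcols(gr)$feature_class <- "window"
  gr
}

#' Count reads in sliding windows
#'
#' Two window dialects are in routine use: 300-bp windows with 20-bp overlap
#' (`step_bp = 280`) for genome-wide sRNA counting, and 300-bp windows with
#' 200-bp overlap (`step_bp = 100`) for the imprinted-region analysis. In
#' `"overlap"` mode (the default, matching interval-intersection tools) a
#' read counts in every window containing its 5' coordinate; in `"assign"`
#' mode it counts once, in the window whose start-offset bin contains the 5'
#' coordinate, so window totals conserve the library.
#'
#' @param reads a single `aligned_reads` data frame or a named list of them
#'   (one per sample).
#' @param genome genome or named contig-length vector.
#' @param window_bp,step_bp window geometry in bp.
#' @param mode `"overlap"` or `"assign"`.
#' @param samples optional sample metadata (`sample_id`, `genotype`,
#'   `replicate`); defaults to WT replicates named after the list.
#' @return A `count_set` whose features are the windows.
#' @export
count_windows <- function(reads, genome, window_bp = 300, step_bp = 100,
                          mode = c("overlap", "assign"), samples = NULL) {
  mode <- match.arg(mode)
  win <- tile_windows(genome, window_bp, step_bp)
  count_in_features(reads, win, samples, mode = mode, step_bp = step_bp)
}

#' Count reads over annotated features
#'
#' Per-feature, per-sample read counts using the 5'-start containment rule
#' (ties to the earlier coordinate-sorted feature). Feature classes are kept
#' so the reference-feature normalization downstream can split genic/miRNA
#' loci from TEs.
#'
#' @param reads a single `aligned_reads` data frame or a named list of them.
#' @param features a `GRanges` with `feature_id` and `feature_class`.
#' @param samples optional sample metadata.
#' @return A `count_set`.
#' @export
count_features <- function(reads, features, samples = NULL) {
  count_in_features(reads, features, samples, mode = "first")
}

count_in_features <- function(reads, features, samples, mode,
                              step_bp = NULL) {
  if (is.data.frame(reads)) reads <- list(sample1 = reads)
  if (is.null(names(reads)))
    names(reads) <- sprintf("sample%d", seq_along(reads))
  ord <- order(as.character(GenomicRanges::seqnames(features)),
               GenomicRanges::start(features))
  feats <- features[ord]
  counts <- vapply(reads, function(rd) {
    if (nrow(rd) == 0) return(numeric(length(feats)))
    fp <- five_prime(rd)
    if (mode == "assign") {
      # windows within a contig are step-spaced; bin the 5' coordinate
      key <- paste0(as.character(GenomicRanges::seqnames(feats)), ":",
                    GenomicRanges::start(feats))
      bin_start <- (fp - 1L) %/% step_bp * step_bp + 1L
      idx <- match(paste0(rd$chrom, ":", bin_start), key)
      # 5' coordinates in the contig tail past the last window keep
      # conservation by falling back to the last window of the contig
      if (anyNA(idx)) {
        last_by_ctg <- tapply(seq_along(feats),
                              as.character(GenomicRanges::seqnames(feats)),
                              max)
        idx[is.na(idx)] <- last_by_ctg[rd$chrom[is.na(idx)]]
      }
      tab <- table(factor(idx, levels = seq_along(feats)))
      return(as.numeric(tab))
    }
    pos_gr <- GenomicRanges::GRanges(rd$chrom, IRanges::IRanges(fp, fp))
    if (mode == "first") {
      idx <- GenomicRanges::findOverlaps(pos_gr, feats, select = "first")
      tab <- table(factor(idx[!is.na(idx)], levels = seq_along(feats)))
      as.numeric(tab)
    } else {
      hits <- GenomicRanges::findOverlaps(pos_gr, feats)
      tab <- table(factor(S4Vectors::subjectHits(hits),
                          levels = seq_along(feats)))
      as.numeric(tab)
    }
  }, numeric(length(feats)))
  if (is.null(samples))
    samples <- data.frame(sample_id = names(reads), genotype = "WT",
                          replicate = seq_along(reads))
  fdf <- data.frame(feature_id = S4Vectors::mcols(feats)$feature_id,
                    feature_class = S4Vectors::mcols(feats)$feature_class,
                    chrom = as.character(GenomicRanges::seqnames(feats)),
                    start = GenomicRanges::start(feats),
                    end = GenomicRanges::end(feats))
  count_set(counts, fdf, samples)
}

#' Call sRNA clusters from one library
#'
#' Read 5'-start positions are merged into islands, islands closer than
#' `pad` bp are merged, and clusters below `mincov_rpm` reads per million
#' are discarded. Each cluster reports per-size read counts, the fraction of
#' reads in the dicer-typical size range, and a predominant size: the modal
#' length within `[dicermin, dicermax]` when the dicer fraction is at least
#' `predominance_min` and the mode is a strict plurality, otherwise `"none"`
#' (the explicit no-predominant-size category).
#'
#' Multimapped reads either are dropped (`multimapper = "unique"`, default)
#' or contribute weight `1/n_hits` when at least one unique-read 5' start
#' lies within `pad` bp of theirs (`multimapper = "weighted"`).
#'
#' @param reads an `aligned_reads` data frame for a single library.
#' @param library_size total reads in the library (for rpm).
#' @param mincov_rpm minimum cluster coverage, reads per million.
#' @param pad merge distance in bp.
#' @param dicermin,dicermax dicer-typical size range, nt.
#' @param predominance_min minimum dicer fraction for a size call.
#' @param multimapper `"unique"` or `"weighted"`.
#' @return A `data.frame` of clusters: coordinates, `total`, per-size counts
#'   (`n20`..`n25`, `n_other`), `rpm`, `dicer_fraction`, `predominant_size`.
#' @export
call_clusters <- function(reads, library_size, mincov_rpm = 0.5, pad = 75,
                          dicermin = 20, dicermax = 25,
                          predominance_min = 0.8,
                          multimapper = c("unique", "weighted")) {
  multimapper <- match.arg(multimapper)
  if (library_size <= 0) stopf("library_size must be positive")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), total = numeric(), rpm = numeric(),
                      dicer_fraction = numeric(),
                      predominant_size = character())
  if (nrow(reads) == 0) return(empty)
  fp <- five_prime(reads)
  uniq <- reads$n_hits == 1
  if (multimapper == "unique") {
    w <- as.numeric(uniq)
  } else {
    w <- numeric(nrow(reads))
    w[uniq] <- 1
    mm <- which(!uniq)
    if (length(mm) > 0) {
      upos <- GenomicRanges::GRanges(reads$chrom[uniq],
                                     IRanges::IRanges(fp[uniq], fp[uniq]))
      mpos <- GenomicRanges::GRanges(reads$chrom[mm],
                                     IRanges::IRanges(pmax(fp[mm] - pad, 1),
                                                      fp[mm] + pad))
      near <- GenomicRanges::countOverlaps(mpos, upos) > 0
      w[mm[near]] <- 1 / reads$n_hits[mm[near]]
    }
  }
  keep <- w > 0
  if (!any(keep)) return(empty)
  fp <- fp[keep]
  w <- w[keep]
  chrom <- reads$chrom[keep]
  len <- reads$length[keep]
  pos_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(fp, fp))
  islands <- GenomicRanges::reduce(pos_gr, min.gapwidth = pad)
  idx <- GenomicRanges::findOverlaps(pos_gr, islands, select = "first")
  sizes <- dicermin:dicermax
  size_lab <- ifelse(len %in% sizes, as.character(len), "other")
  tab <- tapply(w, list(factor(idx, levels = seq_along(islands)),
                        factor(size_lab, levels = c(sizes, "other"))),
                sum, default = 0)
  total <- rowSums(tab)
  rpm <- 1e6 * total / library_size
  dicer <- rowSums(tab[, as.character(sizes), drop = FALSE])
  dicer_fraction <- ifelse(total > 0, dicer / total, 0)
  predominant <- apply(tab[, as.character(sizes), drop = FALSE], 1,
                       function(v) {
                         o <- order(v, decreasing = TRUE)
                         if (v[o[1]] > 0 && v[o[1]] > v[o[2]])
                           as.character(sizes[o[1]]) else "none"
                       })
  predominant[dicer_fraction < predominance_min] <- "none"
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(islands)),
                    start = GenomicRanges::start(islands),
                    end = GenomicRanges::end(islands),
                    total = as.numeric(total), rpm = as.numeric(rpm),
                    dicer_fraction = as.numeric(dicer_fraction),
                    predominant_size = predominant)
  size_counts <- as.data.frame(tab)
  names(size_counts) <- c(sprintf("n%d", sizes), "n_other")
  out <- cbind(out, size_counts)
  out <- out[out$rpm >= mincov_rpm, , drop = FALSE]
  rownames(out) <- NULL
  out
}
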