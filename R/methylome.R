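#' Annotate cytosine context from the genome
#'
#' Labels each methylation call CG/CHG/CHH from its strand-appropriate
#' trinucleotide (read 5'->3' on the cytosine's strand; H = A, C or T).
#' Cytosines within 2 bp of a contig end, whose context cannot be
#' determined, are dropped. A call at a non-cytosine reference position is
#' a hard error.
#'
#' @param calls methylation-call data frame (see [read_cx()]).
#' @param genome the reference genome.
#' @return `calls` with the `context` column (re)computed, end-of-contig
#'   calls removed.
#' @export
pileup_contexts <- function(calls, genome) {
  lens <- contig_lengths(genome)
  out <- vector("list", length(unique(calls$chrom)))
  ctx <- rep(NA_character_, nrow(calls))
  for (ctg in unique(calls$chrom)) {
    idx <- which(calls$chrom == ctg)
    seq_chr <- as.character(genome[[ctg]])
    pos <- calls$pos[idx]
    minus <- calls$strand[idx] == "-"
    base <- substring(seq_chr, pos, pos)
    want <- ifelse(minus, "G", "C")
    if (any(base != want))
      stopf("methylation call at non-cytosine position %s:%d (strand %s)",
            ctg, pos[base != want][1],
            calls$strand[idx][base != want][1])
    determinable <- ifelse(minus, pos - 2L >= 1L, pos + 2L <= lens[ctg])
    tri <- character(length(pos))
    plus_i <- !minus & determinable
    if (any(plus_i))
      tri[plus_i] <- substring(seq_chr, pos[plus_i], pos[plus_i] + 2L)
    minus_i <- minus & determinable
    if (any(minus_i)) {
      raw <- substring(seq_chr, pos[minus_i] - 2L, pos[minus_i])
      tri[minus_i] <- revcomp(raw)
    }
    b2 <- substring(tri, 2, 2)
    b3 <- substring(tri, 3, 3)
    this <- rep(NA_character_, length(pos))
    this[determinable & b2 == "G"] <- "CG"
    this[determinable & b2 != "G" & b3 == "G"] <- "CHG"
    this[determinable & b2 != "G" & b3 != "G"] <- "CHH"
    # trinucleotides containing N have no defined context
    this[grepl("N", tri)] <- NA_character_
    ctx[idx] <- this
  }
  calls$context <- ctx
  out <- calls[!is.na(ctx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bisulfite conversion QC on the chloroplast
#'
#' The chloroplast genome is unmethylated, so any apparent methylation there
#' measures bisulfite conversion failure. The conversion rate is
#' `100 * (1 - sum(methylated) / sum(total))` over chloroplast cytosines
#' with at least `min_depth` reads; libraries below `floor` are flagged.
#'
#' @param calls methylation-call data frame.
#' @param chloroplast_contig contig name of the chloroplast.
#' @param min_depth minimum reads per cytosine to enter the estimate.
#' @param floor QC floor in percent (default 98).
#' @return List: `conversion_rate` (percent), `pass`, `n_cytosines`.
#' @export
conversion_qc <- function(calls, chloroplast_contig, min_depth = 10,
                          floor = 98) {
  sel <- calls$chrom == chloroplast_contig & calls$n_total >= min_depth
  if (!any(sel))
    stopf("no chloroplast cytosine with depth >= %d", min_depth)
  rate <- 100 * (1 - sum(calls$n_meth[sel]) / sum(calls$n_total[sel]))
  list(conversion_rate = rate, pass = rate >= floor,
       n_cytosines = sum(sel))
}

#' Join two conditions' methylation calls on common informative cytosines
#'
#' Aggregates calls over alleles per cytosine and keeps cytosines covered
#' (informative) in both conditions -- the unit entering windowed
#' comparison.
#'
#' @param calls_a,calls_b methylation-call data frames with `context` set.
#' @return Data frame: `chrom`, `pos`, `strand`, `context`, `m_a`, `t_a`,
#'   `m_b`, `t_b`.
#' @export
methyl_join <- function(calls_a, calls_b) {
  agg <- function(calls) {
    key <- paste(calls$chrom, calls$pos, calls$strand, sep = "\r")
    m <- rowsum(calls$n_meth, key)
    t <- rowsum(calls$n_total, key)
    i <- match(rownames(m), key)
    data.frame(key = rownames(m), chrom = calls$chrom[i],
               pos = calls$pos[i], strand = calls$strand[i],
               context = calls$context[i], m = m[, 1], t = t[, 1])
  }
  a <- agg(calls_a)
  b <- agg(calls_b)
  a <- a[a$t > 0, ]
  b <- b[b$t > 0, ]
  i <- match(a$key, b$key)
  keep <- !is.na(i)
  out <- data.frame(chrom = a$chrom[keep], pos = a$pos[keep],
                    strand = a$strand[keep], context = a$context[keep],
                    m_a = a$m[keep], t_a = a$t[keep],
                    m_b = b$m[i[keep]], t_b = b$t[i[keep]])
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Windowed methylation for a condition pair
#'
#' Sliding windows (default 300 bp, 100-bp step) per context. A window is
#' comparable when it holds at least `min_common_c` cytosines informative
#' in both conditions and the informative cytosines average at least
#' `min_depth` reads in each condition (set `strict_depth = TRUE` to
#' require the depth per cytosine instead; the mean-depth reading keeps
#' usable windows at realistic coverage). Window methylation is the
#' coverage-weighted percent `100 * sum(m) / sum(t)`.
#'
#' @param joint output of [methyl_join()].
#' @param genome genome or named contig-length vector (for tiling).
#' @param window,step window geometry, bp.
#' @param min_common_c minimum common informative cytosines.
#' @param min_depth depth requirement, reads per cytosine.
#' @param strict_depth if `TRUE`, every cytosine must meet `min_depth`.
#' @return Data frame of comparable windows: `chrom`, `start`, `end`,
#'   `context`, `n_common`, per-condition sums and percents, `delta`
#'   (B minus A).
#' @export
window_methylation <- function(joint, genome, window = 300, step = 100,
                               min_common_c = 3, min_depth = 6,
                               strict_depth = FALSE) {
  win <- tile_windows(genome, window, step)
  cyt <- GenomicRanges::GRanges(joint$chrom,
                                IRanges::IRanges(joint$pos, joint$pos))
  hits <- GenomicRanges::findOverlaps(cyt, win)
  ci <- S4Vectors::queryHits(hits)
  wi <- S4Vectors::subjectHits(hits)
  grp <- paste(wi, joint$context[ci], sep = "\r")
  n_common <- rowsum(rep(1L, length(ci)), grp)
  m_a <- rowsum(joint$m_a[ci], grp)
  t_a <- rowsum(joint$t_a[ci], grp)
  m_b <- rowsum(joint$m_b[ci], grp)
  t_b <- rowsum(joint$t_b[ci], grp)
  if (strict_depth) {
    ok_a <- rowsum(as.integer(joint$t_a[ci] >= min_depth), grp)
    ok_b <- rowsum(as.integer(joint$t_b[ci] >= min_depth), grp)
    depth_ok <- ok_a[, 1] == n_common[, 1] & ok_b[, 1] == n_common[, 1]
  } else {
    depth_ok <- t_a[, 1] / n_common[, 1] >= min_depth &
      t_b[, 1] / n_common[, 1] >= min_depth
  }
  keys <- strsplit(rownames(n_common), "\r", fixed = TRUE)
  widx <- as.integer(vapply(keys, `[`, "", 1))
  ctx <- vapply(keys, `[`, "", 2)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(win))[widx],
                    start = GenomicRanges::start(win)[widx],
                    end = GenomicRanges::end(win)[widx],
                    context = ctx, n_common = n_common[, 1],
                    m_a = m_a[, 1], t_a = t_a[, 1],
                    m_b = m_b[, 1], t_b = t_b[, 1])
  out$percent_a <- 100 * out$m_a / out$t_a
  out$percent_b <- 100 * out$m_b / out$t_b
  out$delta <- out$percent_b - out$percent_a
  out <- out[out$n_common >= min_common_c & depth_ok, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$context), ]
  rownames(out) <- NULL
  out
}

#' Window-level maternal DNA read fraction
#'
#' Per-window maternal fraction of allele-assigned bisulfite reads,
#' 100 * maternal / (maternal + paternal), using the allele labels on the
#' methylation calls. Windows with no allele-informative reads get `NA`.
#'
#' @param calls methylation-call data frame (with `allele` labels).
#' @param genome genome or contig lengths.
#' @param window,step window geometry, bp.
#' @return Data frame: `chrom`, `start`, `end`, `maternal`, `paternal`,
#'   `percent_maternal`.
#' @export
window_dosage <- function(calls, genome, window = 300, step = 100) {
  win <- tile_windows(genome, window, step)
  cyt <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, calls$pos))
  hits <- GenomicRanges::findOverlaps(cyt, win)
  ci <- S4Vectors::queryHits(hits)
  wi <- S4Vectors::subjectHits(hits)
  f <- factor(wi, levels = seq_along(win))
  mat <- tapply(calls$n_total[ci] * (calls$allele[ci] == "maternal"), f,
                sum, default = 0)
  pat <- tapply(calls$n_total[ci] * (calls$allele[ci] == "paternal"), f,
                sum, default = 0)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(win)),
                    start = GenomicRanges::start(win),
                    end = GenomicRanges::end(win),
                    maternal = as.numeric(mat), paternal = as.numeric(pat))
  inf <- out$maternal + out$paternal
  out$percent_maternal <- ifelse(inf > 0, 100 * out$maternal / inf,
                                 NA_real_)
  out
}

#' Dosage filter on methylation windows
#'
#' Endosperm carries 2 maternal : 1 paternal genomes, so windows whose
#' maternal DNA read fraction strays from 67 +/- 15 percent (inclusive
#' bounds, i.e. [52, 82]) indicate allele-specific coverage loss and are
#' excluded from methylation comparison; windows with no allele-informative
#' reads are dropped.
#'
#' @param windows window data frame (from [window_methylation()]).
#' @param dosage output of [window_dosage()] on the same geometry.
#' @param center,tolerance acceptance band, percent maternal.
#' @return The retained subset of `windows`.
#' @export
dosage_filter <- function(windows, dosage, center = 67, tolerance = 15) {
  key <- function(d) paste(d$chrom, d$start, sep = "\r")
  pm <- dosage$percent_maternal[match(key(windows), key(dosage))]
  keep <- !is.na(pm) & pm >= center - tolerance & pm <= center + tolerance
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-genotype replicate variability mask
#'
#' Windows whose between-replicate methylation difference already meets the
#' context's DMR threshold are unreliable; they are collected and merged
#' into an exclusion set applied to between-genotype comparison.
#'
#' @param rep_windows output of [window_methylation()] run on the two
#'   replicates of one genotype (replicate 1 as condition A, 2 as B).
#' @param thresholds named context thresholds, percent.
#' @return A `GRanges` of masked regions with a `context` column.
#' @export
replicate_mask <- function(rep_windows,
                           thresholds = c(CHH = 10, CHG = 20, CG = 30)) {
  bad <- rep_windows[abs(rep_windows$delta) >=
                       thresholds[rep_windows$context], , drop = FALSE]
  if (nrow(bad) == 0) return(GenomicRanges::GRanges())
  grl <- lapply(split(bad, bad$context), function(d) {
    g <- GenomicRanges::reduce(
      GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end)))
    S4Vectors::mcols(g)$context <- d$context[1]
    g
  })
  suppressWarnings(do.call(c, unname(grl)))
}

#' Call differentially methylated regions
#'
#' Windows whose between-genotype difference meets the context threshold
#' (10% CHH, 20% CHG, 30% CG) are marked; overlapping marked windows of the
#' same context and direction are merged into DMRs (mixed-direction windows
#' are never merged) and per-DMR methylation is recomputed over the merged
#' span from the underlying cytosines. Replicates are pooled per genotype
#' before this comparison.
#'
#' @param windows comparable windows from [window_methylation()] (after any
#'   dosage filtering).
#' @param joint the [methyl_join()] table the windows were built from, used
#'   to recompute percent methylation over merged spans.
#' @param thresholds named context thresholds, percent.
#' @param mask optional `GRanges` exclusion set (see [replicate_mask()]);
#'   windows overlapping a masked region of the same context are dropped.
#' @return Data frame of DMRs: `chrom`, `start`, `end`, `context`,
#'   `direction` (`hyper`/`hypo`, B vs A), `percent_a`, `percent_b`,
#'   `n_windows`.
#' @export
call_dmrs <- function(windows, joint,
                      thresholds = c(CHH = 10, CHG = 20, CG = 30),
                      mask = NULL) {
  marked <- windows[abs(windows$delta) >= thresholds[windows$context], ,
                    drop = FALSE]
  if (!is.null(mask) && length(mask) > 0 && nrow(marked) > 0) {
    wgr <- GenomicRanges::GRanges(marked$chrom,
                                  IRanges::IRanges(marked$start,
                                                   marked$end))
    drop <- rep(FALSE, nrow(marked))
    for (ctx in unique(marked$context)) {
      msk <- mask[S4Vectors::mcols(mask)$context == ctx]
      if (length(msk) == 0) next
      sel <- marked$context == ctx
      drop[sel] <- GenomicRanges::countOverlaps(wgr[sel], msk) > 0
    }
    marked <- marked[!drop, , drop = FALSE]
  }
  if (nrow(marked) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      direction = character(), percent_a = numeric(),
                      percent_b = numeric(), n_windows = integer()))
  marked$direction <- ifelse(marked$delta > 0, "hyper", "hypo")
  pieces <- split(marked, paste(marked$context, marked$direction))
  res <- lapply(pieces, function(d) {
    gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end))
    merged <- GenomicRanges::reduce(gr)
    nw <- GenomicRanges::countOverlaps(merged, gr)
    cyt_sel <- joint$context == d$context[1]
    cyt <- GenomicRanges::GRanges(joint$chrom[cyt_sel],
                                  IRanges::IRanges(joint$pos[cyt_sel],
                                                   joint$pos[cyt_sel]))
    hits <- GenomicRanges::findOverlaps(cyt, merged)
    f <- factor(S4Vectors::subjectHits(hits), levels = seq_along(merged))
    ji <- which(cyt_sel)[S4Vectors::queryHits(hits)]
    pa <- 100 * tapply(joint$m_a[ji], f, sum, default = 0) /
      pmax(tapply(joint$t_a[ji], f, sum, default = 0), 1)
    pb <- 100 * tapply(joint$m_b[ji], f, sum, default = 0) /
      pmax(tapply(joint$t_b[ji], f, sum, default = 0), 1)
    data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
               start = GenomicRanges::start(merged),
               end = GenomicRanges::end(merged),
               context = d$context[1], direction = d$direction[1],
               percent_a = as.numeric(pa), percent_b = as.numeric(pb),
               n_windows = as.integer(nw))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$context), ]
  rownames(out) <- NULL
  out
}
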