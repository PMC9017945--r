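#' Read a reference genome from FASTA
#'
#' Loads all records in file order, uppercases the sequence and validates the
#' alphabet. The genome provides the shared coordinate frame for every other
#' operation; internal coordinates throughout the package are 1-based closed
#' (the Bioconductor convention), with conversions to and from 0-based formats
#' performed at the I/O boundary.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  if (file.size(path) == 0) {
    warnf("empty FASTA file: %s", path)
    return(Biostrings::DNAStringSet())
  }
  # read without an alphabet first so invalid characters are reported with
  # their contig and position rather than a low-level parser error
  raw <- toupper(as.character(Biostrings::readBStringSet(path)))
  # FASTA descriptions may carry trailing comments; the contig name is word 1
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw)))
    stopf("duplicate contig name: %s", names(raw)[duplicated(names(raw))][1])
  for (i in seq_along(raw)) {
    hit <- regexpr("[^ACGTN]", raw[[i]])
    if (hit > 0)
      stopf("non-nucleotide character '%s' in contig %s at position %d",
            substr(raw[[i]], hit, hit), names(raw)[i], as.integer(hit))
  }
  Biostrings::DNAStringSet(raw)
}

#' Write a genome to FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a biallelic SNP table from a VCF subset
#'
#' Parses the CHROM/POS/REF/ALT columns of a VCF-style file (POS 1-based).
#' Only biallelic single-nucleotide substitutions are retained: indels and
#' multi-allelic records are skipped and counted, because the parental
#' pseudogenome is built by base substitution only and must preserve
#' coordinate systems. Records are sorted by (contig, position).
#'
#' @param path path to the VCF-subset file. Lines starting with `#` are
#'   ignored. Either 4 columns (CHROM POS REF ALT) or standard VCF layout
#'   (CHROM POS ID REF ALT ...) are accepted.
#' @param genome optional genome; when supplied, every REF base is checked
#'   against it and a mismatch is a hard error.
#' @param parent_of_ref which parental genome carries the reference base;
#'   in a Ler x Col-0 cross aligned to the Col-0 reference the reference
#'   allele is paternal.
#' @return A `data.frame` of class `snp_table` with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `parent_of_ref`, and attribute `n_skipped`.
#' @export
read_snps <- function(path, genome = NULL,
                      parent_of_ref = c("paternal", "maternal")) {
  parent_of_ref <- match.arg(parent_of_ref)
  if (!file.exists(path)) stopf("SNP file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           colClasses = "character",
                           col.names = paste0("V", 1:10), fill = TRUE,
                           blank.lines.skip = TRUE)
  if (nrow(tab) == 0) {
    snps <- data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       parent_of_ref = character())
    return(snp_table(snps, n_skipped = 0L))
  }
  # standard VCF has ID in column 3; the bare subset has REF there
  ref_col <- if (all(grepl("^[ACGTNacgtn]+$", tab$V3))) 3L else 4L
  snps <- data.frame(chrom = tab$V1,
                     pos = as.integer(tab$V2),
                     ref = toupper(tab[[ref_col]]),
                     alt = toupper(tab[[ref_col + 1L]]),
                     parent_of_ref = parent_of_ref)
  keep <- nchar(snps$ref) == 1 & nchar(snps$alt) == 1 &
    snps$ref %in% c("A", "C", "G", "T") & snps$alt %in% c("A", "C", "G", "T") &
    snps$ref != snps$alt
  n_skipped <- sum(!keep)
  snps <- snps[keep, , drop = FALSE]
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  if (any(duplicated(snps[c("chrom", "pos")])))
    stopf("duplicate SNP positions in %s", path)
  if (!is.null(genome)) {
    for (ctg in unique(snps$chrom)) {
      if (!ctg %in% names(genome))
        stopf("SNP contig %s absent from genome", ctg)
      idx <- snps$chrom == ctg
      here <- substring(as.character(genome[[ctg]]), snps$pos[idx],
                        snps$pos[idx])
      bad <- which(here != snps$ref[idx])
      if (length(bad) > 0)
        stopf("SNP REF mismatch at %s:%d (genome has %s, record says %s)",
              ctg, snps$pos[idx][bad[1]], here[bad[1]],
              snps$ref[idx][bad[1]])
    }
  }
  snp_table(snps, n_skipped = n_skipped)
}

snp_table <- function(df, n_skipped = 0L) {
  structure(df, class = c("snp_table", "data.frame"),
            n_skipped = as.integer(n_skipped))
}

#' Write a SNP table as a minimal VCF subset
#' @param snps a `snp_table`.
#' @param path output path.
#' @export
write_snps <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT"), con)
  if (nrow(snps) > 0)
    utils::write.table(data.frame(snps$chrom, snps$pos, ".", snps$ref,
                                  snps$alt),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' Read genomic intervals from BED or GFF3
#'
#' BED intervals (0-based half-open) and GFF3 intervals (1-based closed) are
#' both converted to the internal 1-based closed representation.
#'
#' @param path input path.
#' @param dialect `"bed"` or `"gff3"`.
#' @param feature_class either a single class recycled to every record, or
#'   `NULL` to use `class_map`.
#' @param class_map named character vector mapping BED names / GFF3 `type`
#'   values to feature classes; unmapped records get `"other_ncRNA"`.
#' @param genome optional genome for bounds checking.
#' @return A [GenomicRanges::GRanges] with metadata columns `feature_id` and
#'   `feature_class`.
#' @export
read_intervals <- function(path, dialect = c("bed", "gff3"),
                           feature_class = NULL, class_map = NULL,
                           genome = NULL) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path,
                            format = if (dialect == "bed") "BED" else "GFF3")
  if (any(GenomicRanges::width(gr) < 1))
    stopf("interval with start >= end at record %d of %s",
          which(GenomicRanges::width(gr) < 1)[1], path)
  if (dialect == "bed") {
    ids <- S4Vectors::mcols(gr)$name
    if (is.null(ids) || all(is.na(ids)))
      ids <- sprintf("feat_%d", seq_along(gr))
    key <- ids
  } else {
    m <- S4Vectors::mcols(gr)
    ids <- m$ID
    if (is.null(ids)) ids <- m$Name
    if (is.null(ids)) ids <- sprintf("feat_%d", seq_along(gr))
    ids[is.na(ids)] <- sprintf("feat_%d", which(is.na(ids)))
    key <- as.character(m$type)
  }
  if (!is.null(feature_class)) {
    cls <- rep_len(feature_class, length(gr))
  } else if (!is.null(class_map)) {
    cls <- unname(class_map[key])
    cls[is.na(cls)] <- "other_ncRNA"
  } else {
    cls <- rep("other_ncRNA", length(gr))
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(feature_id = as.character(ids),
                                               feature_class = cls)
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    ctg <- as.character(GenomicRanges::seqnames(gr))
    if (!all(ctg %in% names(lens)))
      stopf("interval contig %s absent from genome",
            setdiff(ctg, names(lens))[1])
    if (any(GenomicRanges::end(gr) > lens[ctg]))
      stopf("interval extends past contig end at record %d",
            which(GenomicRanges::end(gr) > lens[ctg])[1])
  }
  gr
}

#' Write intervals as BED6
#' @param gr a `GRanges` with `feature_id` metadata.
#' @param path output path.
#' @export
write_intervals <- function(gr, path) {
  out <- gr
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(gr)$feature_id %||% sprintf("feat_%d",
                                                        seq_along(gr)))
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read aligned reads from the SAM-like TSV dialect
#'
#' The dialect is a 6-column tab-separated table: `read_id`, `contig`,
#' `start` (0-based leftmost reference coordinate of the alignment),
#' `strand`, `sequence` (as sequenced, 5'->3'), `n_hits` (number of equally
#' good alignment locations). Malformed lines are counted and skipped up to
#' `max_bad_frac`; a contig absent from the genome is a hard error.
#'
#' @param path input path; lines starting with `#` are ignored.
#' @param genome genome (or named contig-length vector) for validation.
#' @param max_bad_frac tolerated fraction of malformed lines.
#' @return A `data.frame` of class `aligned_reads` with columns `read_id`,
#'   `chrom`, `start` (1-based leftmost), `strand`, `sequence`, `length`,
#'   `n_hits`, and attribute `n_skipped`.
#' @export
read_alignments <- function(path, genome, max_bad_frac = 0.01) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(aligned_reads_empty())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  ok <- nf == 6
  flat <- unlist(parts[ok], use.names = FALSE)
  m <- matrix(flat, ncol = 6, byrow = TRUE)
  df <- data.frame(read_id = m[, 1], chrom = m[, 2],
                   start = suppressWarnings(as.integer(m[, 3])) + 1L,
                   strand = m[, 4], sequence = toupper(m[, 5]),
                   n_hits = suppressWarnings(as.integer(m[, 6])))
  df$length <- nchar(df$sequence)
  lens <- contig_lengths(genome)
  known <- df$chrom %in% names(lens)
  if (!all(known))
    stopf("alignment contig %s absent from genome",
          setdiff(df$chrom, names(lens))[1])
  good <- !is.na(df$start) & df$start >= 1 & df$strand %in% c("+", "-") &
    df$length > 0 & grepl("^[ACGTN]+$", df$sequence) &
    !is.na(df$n_hits) & df$n_hits >= 1 &
    (df$start + df$length - 1L) <= lens[df$chrom]
  n_skipped <- sum(!ok) + sum(!good)
  if (n_skipped / length(lines) > max_bad_frac)
    stopf("%d of %d alignment lines malformed (tolerance %.3f)",
          n_skipped, length(lines), max_bad_frac)
  df <- df[good, c("read_id", "chrom", "start", "strand", "sequence",
                   "length", "n_hits")]
  rownames(df) <- NULL
  structure(df, class = c("aligned_reads", "data.frame"),
            n_skipped = as.integer(n_skipped))
}

aligned_reads_empty <- function() {
  structure(data.frame(read_id = character(), chrom = character(),
                       start = integer(), strand = character(),
                       sequence = character(), length = integer(),
                       n_hits = integer()),
            class = c("aligned_reads", "data.frame"), n_skipped = 0L)
}

#' Write aligned reads in the SAM-like TSV dialect
#' @param reads an `aligned_reads` data frame.
#' @param path output path.
#' @export
write_alignments <- function(reads, path) {
  out <- data.frame(reads$read_id, reads$chrom, reads$start - 1L,
                    reads$strand, reads$sequence, reads$n_hits)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# 5'-end reference coordinate of each read (strand-aware)
five_prime <- function(reads) {
  ifelse(reads$strand == "-", reads$start + reads$length - 1L, reads$start)
}

reads_granges <- function(reads) {
  GenomicRanges::GRanges(reads$chrom,
                         IRanges::IRanges(reads$start,
                                          reads$start + reads$length - 1L))
}

#' Write a value track as bedGraph
#'
#' @param track a `GRanges` with a numeric `score` column, or a data frame
#'   with `chrom`, `start`, `end` (1-based closed) and `score`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (is.data.frame(track))
    track <- GenomicRanges::GRanges(track$chrom,
                                    IRanges::IRanges(track$start, track$end),
                                    score = track$score)
  if (is.unsorted(order(as.character(GenomicRanges::seqnames(track)),
                        GenomicRanges::start(track)))) {
    warnf("bedGraph track was unsorted; sorting before writing")
  }
  track <- GenomicRanges::sort(track)
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph track
#' @param path input path.
#' @return A `GRanges` with a `score` column (1-based closed internally).
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Read per-cytosine methylation calls (CX-style TSV)
#'
#' Columns: `contig`, `pos` (1-based position of the cytosine on its strand),
#' `strand`, `context`, `count_methylated`, `count_unmethylated`, `allele`.
#'
#' @param path input path (tab-separated with header).
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`, `context`,
#'   `n_meth`, `n_total`, `allele`.
#' @export
read_cx <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("contig", "pos", "strand", "context", "count_methylated",
            "count_unmethylated", "allele")
  if (!all(need %in% names(tab)))
    stopf("CX table missing columns: %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  out <- data.frame(chrom = tab$contig, pos = as.integer(tab$pos),
                    strand = tab$strand, context = tab$context,
                    n_meth = as.integer(tab$count_methylated),
                    n_total = as.integer(tab$count_methylated) +
                      as.integer(tab$count_unmethylated),
                    allele = tab$allele)
  if (any(out$n_meth > out$n_total) || any(out$n_meth < 0))
    stopf("methylated count outside [0, total]")
  out
}

#' Write per-cytosine methylation calls (CX-style TSV)
#' @param calls data frame as returned by [read_cx()].
#' @param path output path.
#' @export
write_cx <- function(calls, path) {
  out <- data.frame(contig = calls$chrom, pos = calls$pos,
                    strand = calls$strand, context = calls$context,
                    count_methylated = calls$n_meth,
                    count_unmethylated = calls$n_total - calls$n_meth,
                    allele = calls$allele)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
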