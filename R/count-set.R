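#' Build a count set (features x samples with metadata)
#'
#' The shared container for sRNA window/feature counts, mRNA gene counts and
#' per-nucleotide 5'-end counts: a non-negative numeric matrix plus feature
#' and sample annotation, in the style of an edgeR `DGEList`.
#'
#' @param counts numeric matrix (features x samples), non-negative.
#' @param features data frame with at least `feature_id` and `feature_class`;
#'   one row per matrix row.
#' @param samples data frame with at least `sample_id`, `genotype` (one of
#'   `WT`, `mat_het`, `pat_het`, `null`) and `replicate`; one row per column.
#' @return A list of class `count_set`.
#' @export
count_set <- function(counts, features, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (nrow(counts) != nrow(features))
    stopf("counts rows (%d) != feature rows (%d)", nrow(counts),
          nrow(features))
  if (ncol(counts) != nrow(samples))
    stopf("counts columns (%d) != sample rows (%d)", ncol(counts),
          nrow(samples))
  if (!all(c("feature_id", "feature_class") %in% names(features)))
    stopf("features needs feature_id and feature_class")
  if (!all(c("sample_id", "genotype", "replicate") %in% names(samples)))
    stopf("samples needs sample_id, genotype and replicate")
  if (!all(samples$genotype %in% GENOTYPES))
    stopf("unknown genotype label: %s",
          setdiff(samples$genotype, GENOTYPES)[1])
  rownames(counts) <- features$feature_id
  colnames(counts) <- samples$sample_id
  rownames(features) <- NULL
  rownames(samples) <- NULL
  structure(list(counts = counts, features = features, samples = samples),
            class = "count_set")
}

#' @export
print.count_set <- function(x, ...) {
  cat(sprintf("count_set: %d features x %d samples\n", nrow(x$counts),
              ncol(x$counts)))
  cat("classes:", paste(sort(unique(x$features$feature_class)),
                        collapse = ", "), "\n")
  cat("genotypes:", paste(unique(x$samples$genotype), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_set <- function(x) dim(x$counts)

# subset a count_set by feature index/logical and sample index/logical
cs_subset <- function(cs, i = NULL, j = NULL) {
  if (!is.null(i)) {
    cs$counts <- cs$counts[i, , drop = FALSE]
    cs$features <- cs$features[i, , drop = FALSE]
    rownames(cs$features) <- NULL
  }
  if (!is.null(j)) {
    cs$counts <- cs$counts[, j, drop = FALSE]
    cs$samples <- cs$samples[j, , drop = FALSE]
    rownames(cs$samples) <- NULL
  }
  cs
}

# column-bind two count_sets sharing the same features
cs_cbind <- function(a, b) {
  stopifnot(identical(a$features$feature_id, b$features$feature_id))
  count_set(cbind(a$counts, b$counts), a$features,
            rbind(a$samples, b$samples))
}
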