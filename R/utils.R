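`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and labels
#'
#' Each simulated library gets its own pseudo-random stream derived from the
#' master seed and a set of string labels (dataset, genotype, replicate) by a
#' stable polynomial hash, so adding a library never perturbs existing ones.
#'
#' @param seed master integer seed.
#' @param ... character or numeric labels identifying the stream.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
stream_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  m <- 2147483647  # 2^31 - 1, keeps every derived seed a valid R integer
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

# evaluate expr under a local RNG stream, restoring global RNG state
with_stream <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# contig lengths from a DNAStringSet or a named numeric vector
contig_lengths <- function(genome) {
  if (is.numeric(genome)) {
    if (is.null(names(genome))) stopf("contig lengths must be named")
    return(genome)
  }
  stats::setNames(Biostrings::width(genome), names(genome))
}

# reverse-complement a character vector of sequences
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
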