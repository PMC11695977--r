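#' @importFrom S4Vectors queryHits subjectHits elementNROWS
#' @importFrom stats p.adjust pt quantile rnbinom rpois runif rnorm rlnorm fisher.test wilcox.test setNames aggregate sd var fivenum
#' @importFrom utils write.table read.table head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generators do not perturb each other.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE)], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open bin id string, e.g. "chr1:35000-40000"
bin_id <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Overlap queries without the chatty "no sequence levels in common" warning
# raised when query and subject share no chromosome.
quiet_overlaps <- function(q, s) suppressWarnings(GenomicRanges::findOverlaps(q, s))
quiet_count <- function(q, s) suppressWarnings(GenomicRanges::countOverlaps(q, s))
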