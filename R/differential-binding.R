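#' Differential-binding configuration
#'
#' @param fdr_threshold BH-adjusted p-value below which a peak is called
#'   differential in the replicate test.
#' @param loglr_threshold Log10 likelihood-ratio cutoff for the pileup test
#'   (3.84, the chi-squared 1-df critical value at 0.05).
#' @param pseudocount Reads added to normalized counts before log transform /
#'   likelihood evaluation.
#' @return A `diff_config` list.
#' @export
diff_config <- function(fdr_threshold = 0.05, loglr_threshold = 3.84,
                        pseudocount = 1) {
  if (fdr_threshold <= 0 || loglr_threshold <= 0 || pseudocount < 0)
    stop("thresholds must be positive and pseudocount non-negative")
  structure(list(fdr_threshold = fdr_threshold,
                 loglr_threshold = loglr_threshold,
                 pseudocount = pseudocount),
            class = "diff_config")
}

#' Depth-normalize a peak count matrix by reads-in-peaks
#'
#' Each replicate column is scaled by `mean(reads_in_peaks) /
#' reads_in_peaks[j]`, normalizing every replicate to the fraction of reads
#' falling within called peaks (FRiP-style library-size correction).
#'
#' @param counts Numeric matrix, peaks x replicates.
#' @param reads_in_peaks Per-replicate reads-in-peaks totals; defaults to the
#'   column sums over the peak set.
#' @return The normalized matrix.
#' @export
normalize_frip <- function(counts, reads_in_peaks = colSums(counts)) {
  if (any(reads_in_peaks <= 0)) stop("a replicate has zero reads in peaks")
  sweep(counts, 2, mean(reads_in_peaks) / reads_in_peaks, `*`)
}

#' Replicate-aware differential test between two conditions
#'
#' FRiP-normalizes the matrix, log2-transforms with a pseudocount, and tests
#' each peak between the two condition groups with an empirical-Bayes
#' moderated t statistic (limma trend), pooling variance information across
#' peaks so that few-replicate designs retain power; p-values are
#' Benjamini-Hochberg adjusted across peaks. Direction is called from the
#' sign of the treatment-over-reference log2 fold change of normalized means,
#' only for peaks below the FDR threshold.
#'
#' @param counts Numeric matrix, peaks x replicates (rownames are peak ids).
#' @param condition Factor/character of length `ncol(counts)` with exactly two
#'   levels; the first level is the reference (control).
#' @param cfg A [diff_config()].
#' @param reads_in_peaks Optional per-replicate totals for normalization.
#' @return data.frame `peak_id, effect, p, q, direction`
#'   (`lost`/`gained`/`unchanged`, from the treatment's perspective).
#' @export
test_differential <- function(counts, condition, cfg = diff_config(),
                              reads_in_peaks = colSums(counts)) {
  condition <- factor(condition)
  if (nlevels(condition) != 2L)
    stop("exactly two conditions are required")
  if (any(table(condition) < 2L))
    stop("at least two replicates per condition are required")
  norm <- normalize_frip(counts, reads_in_peaks)
  x <- log2(norm + cfg$pseudocount)
  i1 <- which(condition == levels(condition)[1])
  i2 <- which(condition == levels(condition)[2])
  design <- cbind(intercept = 1, treated = as.integer(condition == levels(condition)[2]))
  fit <- limma::eBayes(limma::lmFit(x, design), trend = nrow(x) >= 10)
  p <- fit$p.value[, "treated"]
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1, var)
  v2 <- apply(x[, i2, drop = FALSE], 1, var)
  # degenerate peaks carry no evidence: identical raw counts in every sample
  p[apply(counts, 1, function(r) all(r == r[1]))] <- 1
  p[v1 == 0 & v2 == 0 & m1 == m2] <- 1
  q <- bh_adjust(p)
  effect <- log2((rowMeans(norm[, i2, drop = FALSE]) + cfg$pseudocount) /
                   (rowMeans(norm[, i1, drop = FALSE]) + cfg$pseudocount))
  direction <- ifelse(q < cfg$fdr_threshold & effect < 0, "lost",
                      ifelse(q < cfg$fdr_threshold & effect > 0, "gained",
                             "unchanged"))
  data.frame(peak_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             effect = effect, p = p, q = q, direction = direction,
             stringsAsFactors = FALSE)
}

#' Poisson log-likelihood ratio for a two-condition pileup comparison
#'
#' Counts are scaled to the smaller sequencing depth, a pseudocount is added,
#' and the log10 likelihood ratio of the two-rate model over the common-rate
#' model (rate = the mean of the two scaled counts) is computed under Poisson
#' likelihoods. Peaks with a ratio above `loglr_threshold` are flagged
#' differential, with direction from the sign of the difference (the second
#' condition's perspective: fewer reads there is a loss).
#'
#' @param c1,c2 Counts in condition 1 (reference) and condition 2.
#' @param d1,d2 Total sequencing depths of the two conditions.
#' @param cfg A [diff_config()].
#' @return data.frame `loglr, differential, direction` (vectorized).
#' @export
poisson_loglr <- function(c1, c2, d1, d2, cfg = diff_config()) {
  stopifnot(all(c1 >= 0), all(c2 >= 0), all(d1 > 0), all(d2 > 0))
  dmin <- pmin(d1, d2)
  x1 <- c1 * dmin / d1 + cfg$pseudocount
  x2 <- c2 * dmin / d2 + cfg$pseudocount
  m <- (x1 + x2) / 2
  term <- function(x) ifelse(x > 0, x * log(x / m), 0)
  loglr <- (term(x1) + term(x2)) / log(10)
  diffr <- loglr > cfg$loglr_threshold
  data.frame(loglr = loglr, differential = diffr,
             direction = ifelse(diffr & x2 < x1, "lost",
                                ifelse(diffr & x2 > x1, "gained", "unchanged")),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
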