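#' Contact-map configuration
#'
#' @param bin_width DNA bin width in bp (5-kb resolution).
#' @param trans_distance Minimum gene-to-bin gap, in bp, for a same-chromosome
#'   contact to be called trans (strictly greater than).
#' @param norm_scale Normalization scale: frequencies are contacts per
#'   `norm_scale` valid contacts (contacts per million by default).
#' @return A `contact_config` list.
#' @export
contact_config <- function(bin_width = 5000L, trans_distance = 5e6,
                           norm_scale = 1e6) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (trans_distance <= bin_width) stop("trans_distance must exceed bin_width")
  structure(list(bin_width = as.integer(bin_width),
                 trans_distance = trans_distance,
                 norm_scale = norm_scale),
            class = "contact_config")
}

#' Tile chromosomes into fixed-width genomic bins
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param cfg A [contact_config()].
#' @return data.frame `chrom, start, end, bin` of half-open 0-based bins; the
#'   terminal bin of a chromosome may be short. Zero-length chromosomes are
#'   skipped with a warning.
#' @export
make_bins <- function(chrom_sizes, cfg = contact_config()) {
  if (any(chrom_sizes < 0)) stop("chromosome sizes must be non-negative")
  if (any(chrom_sizes == 0)) {
    warning("skipping zero-length chromosomes: ",
            paste(names(chrom_sizes)[chrom_sizes == 0], collapse = ", "))
    chrom_sizes <- chrom_sizes[chrom_sizes > 0]
  }
  w <- cfg$bin_width
  rows <- lapply(names(chrom_sizes), function(cn) {
    sz <- chrom_sizes[[cn]]
    start <- seq.int(0L, sz - 1L, by = w)
    data.frame(chrom = cn, start = start,
               end = pmin(start + w, sz), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bin <- bin_id(out$chrom, out$start, out$end)
  out
}

#' Assign aligned read pairs to (RNA gene, DNA bin) contacts
#'
#' A pair contributes one raw count iff its DNA part is uniquely mapped (bin
#' chosen by the 5' coordinate of the DNA alignment), both RNA alignments (5'
#' part and 3' mate) are uniquely mapped within the same annotated gene, and
#' the 3' mate carries the RNA 3'-end signature. When genes overlap, the gene
#' with the longest overlap wins; ties drop the pair.
#'
#' @param parts Split-parts table from [extract_chimeras()].
#' @param genes Gene annotation data.frame (`gene_id, chrom, start, end`).
#' @param bins Bin table from [make_bins()].
#' @param cfg A [contact_config()].
#' @return data.frame `rna_gene_id, chrom, start, end, raw_count` with a
#'   `drops` attribute tabulating why pairs were discarded.
#' @export
assign_contacts <- function(parts, genes, bins, cfg = contact_config()) {
  n <- nrow(parts)
  drop_reason <- rep(NA_character_, n)
  ok <- rep(TRUE, n)
  flag <- function(bad, why) {
    new <- bad & ok
    drop_reason[new] <<- why
    ok[new] <<- FALSE
  }
  if ("valid3" %in% names(parts)) flag(!parts$valid3, "invalid_rna3")
  flag(!parts$dna_unique, "dna_not_unique")
  flag(!parts$rna5_unique, "rna5_not_unique")
  flag(!parts$rna3_unique, "rna3_not_unique")

  g5 <- gene_of_interval(parts$rna5_chrom, parts$rna5_pos, parts$rna5_len, genes)
  g3 <- gene_of_interval(parts$rna3_chrom, parts$rna3_pos, parts$rna3_len, genes)
  flag(is.na(g5) | is.na(g3), "rna_outside_gene")
  flag(!is.na(g5) & !is.na(g3) & g5 != g3, "rna_mates_different_genes")

  # 5' coordinate of the DNA alignment: leftmost base on plus, rightmost on
  # minus strand.
  coord <- ifelse(!is.na(parts$dna_strand) & parts$dna_strand == "-",
                  parts$dna_pos + parts$dna_len - 1L, parts$dna_pos)
  bs <- (coord %/% cfg$bin_width) * cfg$bin_width
  key <- paste(parts$dna_chrom, bs)
  bin_i <- match(key, paste(bins$chrom, bins$start))
  flag(is.na(bin_i), "dna_outside_bins")

  kept <- which(ok)
  tab <- table(paste(g5[kept], bins$bin[bin_i[kept]], sep = "\t"))
  parts2 <- strsplit(names(tab), "\t", fixed = TRUE)
  bb <- parse_bin_id(vapply(parts2, `[`, "", 2))
  out <- data.frame(rna_gene_id = vapply(parts2, `[`, "", 1),
                    chrom = bb$chrom, start = bb$start,
                    end = bb$end, raw_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rna_gene_id, out$chrom, out$start), ]
  rownames(out) <- NULL
  attr(out, "drops") <- table(drop_reason[!ok])
  attr(out, "n_valid") <- length(kept)
  out
}

# Longest-overlap gene assignment for an aligned interval; ties and no
# overlap give NA.
gene_of_interval <- function(chrom, pos, len, genes) {
  out <- rep(NA_character_, length(chrom))
  valid <- which(!is.na(chrom))
  if (!length(valid)) return(out)
  q <- GenomicRanges::GRanges(chrom[valid],
                              IRanges::IRanges(pos[valid] + 1L,
                                               pos[valid] + len[valid]))
  s <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- quiet_overlaps(q, s)
  if (!length(hits)) return(out)
  ov <- IRanges::width(IRanges::pintersect(q[queryHits(hits)], s[subjectHits(hits)]))
  d <- data.frame(q = queryHits(hits), s = subjectHits(hits), w = ov)
  d <- d[order(d$q, -d$w), ]
  first <- !duplicated(d$q)
  best <- d[first, ]
  # a tie for the longest overlap drops the pair
  second <- d[!first & !duplicated(d$q[!first]), ]
  tie <- best$q %in% second$q[second$w == best$w[match(second$q, best$q)]]
  best <- best[!tie, ]
  out[valid[best$q]] <- genes$gene_id[best$s]
  out
}

#' Depth-normalize a contact table
#'
#' Adds `normalized_frequency = raw_count * norm_scale / total_valid`, where
#' `total_valid` is the summed raw count of the table, so frequencies sum to
#' `norm_scale` exactly and are comparable across libraries of different
#' depth.
#'
#' @param table Contact table from [assign_contacts()].
#' @param cfg A [contact_config()].
#' @return The table with a `normalized_frequency` column and a `norm_scale`
#'   attribute.
#' @export
normalize_contacts <- function(table, cfg = contact_config()) {
  if (nrow(table) == 0) {
    table$normalized_frequency <- numeric(0)
    attr(table, "norm_scale") <- cfg$norm_scale
    return(table)
  }
  total <- sum(table$raw_count)
  stopifnot(total >= 1)
  table$normalized_frequency <- table$raw_count * cfg$norm_scale / total
  attr(table, "norm_scale") <- cfg$norm_scale
  table
}

#' Classify contacts as cis or trans
#'
#' A contact is trans iff its DNA bin lies on a different chromosome than the
#' RNA's gene locus, or the gap between bin and gene interval strictly exceeds
#' `trans_distance`; otherwise cis. A gap of exactly `trans_distance` is cis.
#'
#' @param table Contact table (`rna_gene_id, chrom, start, end`).
#' @param genes Gene annotation with loci.
#' @param cfg A [contact_config()].
#' @return The table with an `rna_class` column (`"cis"`/`"trans"`).
#' @export
classify_cis_trans <- function(table, genes, cfg = contact_config()) {
  gi <- match(table$rna_gene_id, genes$gene_id)
  if (anyNA(gi)) stop("contact table contains genes absent from the annotation")
  gs <- genes$start[gi]; ge <- genes$end[gi]; gc <- genes$chrom[gi]
  gap <- pmax(table$start - ge, gs - table$end, 0)
  table$rna_class <- ifelse(gc != table$chrom | gap > cfg$trans_distance,
                            "trans", "cis")
  table
}

#' Frequency-stratified contact counts and fold changes
#'
#' Counts unique (gene, bin) contacts of two libraries per normalized
#' interaction-frequency stratum, and the second-over-first fold change per
#' stratum. Strata are left-closed right-open intervals over the per-million
#' frequency scale.
#'
#' @param table_a,table_b Normalized contact tables (same `norm_scale`).
#' @param breaks Ascending stratum edges.
#' @return data.frame `stratum, n_a, n_b, fold_change`; a stratum empty in
#'   `table_a` has fold change NA (undefined), not 0.
#' @export
frequency_distribution <- function(table_a, table_b,
                                   breaks = c(0, 1, 2, 5, 10, 20, Inf)) {
  sa <- attr(table_a, "norm_scale"); sb <- attr(table_b, "norm_scale")
  if (!is.null(sa) && !is.null(sb) && sa != sb)
    stop("contact tables are normalized on different scales")
  lab <- levels(cut(numeric(0), breaks, right = FALSE))
  na <- table(cut(table_a$normalized_frequency, breaks, right = FALSE))
  nb <- table(cut(table_b$normalized_frequency, breaks, right = FALSE))
  data.frame(stratum = lab,
             n_a = as.integer(na), n_b = as.integer(nb),
             fold_change = ifelse(na > 0, as.numeric(nb) / as.numeric(na), NA),
             stringsAsFactors = FALSE)
}

#' Contact frequencies inside versus outside protein-binding peaks
#'
#' Labels each contact's bin by peak containment (any overlap with a called
#' peak) and compares in-peak versus out-of-peak normalized frequencies with a
#' Wilcoxon signed-rank test paired per RNA gene: for every gene with
#' contacts in both groups, its mean in-peak frequency is paired with its mean
#' out-of-peak frequency.
#'
#' @param table Normalized, classified contact table.
#' @param peaks data.frame `chrom, start, end` of peak intervals (half-open).
#' @return List: `in_peak` logical per contact, `pairs` (per-gene means),
#'   `statistic`, `p_value`, plus the two frequency vectors.
#' @export
peak_overlap_frequencies <- function(table, peaks) {
  q <- GenomicRanges::GRanges(table$chrom,
                              IRanges::IRanges(table$start + 1L, table$end))
  s <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1L, peaks$end))
  inp <- quiet_count(q, s) > 0L
  f_in <- table$normalized_frequency[inp]
  f_out <- table$normalized_frequency[!inp]
  gm_in <- tapply(f_in, table$rna_gene_id[inp], mean)
  gm_out <- tapply(f_out, table$rna_gene_id[!inp], mean)
  shared <- intersect(names(gm_in), names(gm_out))
  res <- list(in_peak = inp, freq_in = f_in, freq_out = f_out,
              pairs = data.frame(gene_id = shared,
                                 mean_in = as.numeric(gm_in[shared]),
                                 mean_out = as.numeric(gm_out[shared]),
                                 stringsAsFactors = FALSE),
              statistic = NA_real_, p_value = NA_real_)
  if (length(f_in) == 0 || length(f_out) == 0 || length(shared) == 0) {
    warning("one frequency group is empty; signed-rank test skipped")
    return(res)
  }
  wt <- suppressWarnings(wilcox.test(res$pairs$mean_in, res$pairs$mean_out,
                                     paired = TRUE))
  res$statistic <- unname(wt$statistic)
  res$p_value <- wt$p.value
  res
}

#' Shuffle peaks uniformly within their chromosomes
#'
#' Each peak is relocated uniformly at random on its own chromosome with its
#' length preserved; shuffled peaks must not overlap each other (rejection
#' sampling with a bounded number of retries). Deterministic under `seed`.
#'
#' @param peaks data.frame `chrom, start, end`.
#' @param chrom_sizes Named chromosome lengths.
#' @param seed Integer seed.
#' @param max_tries Retries per peak before giving up.
#' @return The shuffled peak data.frame.
#' @export
shuffle_peaks <- function(peaks, chrom_sizes, seed, max_tries = 1000L) {
  with_seed(seed, {
    out <- peaks
    for (cn in unique(peaks$chrom)) {
      i <- which(peaks$chrom == cn)
      sz <- chrom_sizes[[cn]]
      w <- peaks$end[i] - peaks$start[i]
      if (any(w > sz)) stop("peak longer than its chromosome")
      placed_s <- integer(0); placed_e <- integer(0)
      for (k in seq_along(i)) {
        for (t in seq_len(max_tries)) {
          s <- floor(runif(1) * (sz - w[k] + 1))
          e <- s + w[k]
          if (!any(s < placed_e & e > placed_s)) break
          if (t == max_tries)
            stop("chromosome ", cn, " too crowded to place shuffled peaks")
        }
        placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
      }
      out$start[i] <- placed_s
      out$end[i] <- placed_e
    }
    out
  })
}
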