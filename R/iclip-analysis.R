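#' iCLIP analysis configuration
#'
#' @param score_percentile_drop Proportion of lowest-scored crosslink
#'   positions removed before site merging (global filter).
#' @param site_width Binding-site width in nt (odd).
#' @param min_covered_positions Minimum event-covered positions per site in
#'   the pooled track.
#' @param min_replicate_support Minimum replicates with at least one event
#'   inside a site.
#' @param n_replicates Number of replicate tracks.
#' @param expression_cpm_threshold Counts-per-million above which a gene
#'   counts as expressed (the enrichment-test universe).
#' @param top_k Number of top-ranked candidate lncRNAs to select.
#' @return An `iclip_config` list.
#' @export
iclip_config <- function(score_percentile_drop = 0.02, site_width = 7L,
                         min_covered_positions = 3L, min_replicate_support = 4L,
                         n_replicates = 5L, expression_cpm_threshold = 5,
                         top_k = 16L) {
  if (score_percentile_drop < 0 || score_percentile_drop >= 1)
    stop("score_percentile_drop must be in [0, 1)")
  if (site_width %% 2 != 1) stop("site_width must be odd")
  if (min_replicate_support > n_replicates)
    stop("min_replicate_support cannot exceed n_replicates")
  structure(list(score_percentile_drop = score_percentile_drop,
                 site_width = as.integer(site_width),
                 min_covered_positions = as.integer(min_covered_positions),
                 min_replicate_support = as.integer(min_replicate_support),
                 n_replicates = as.integer(n_replicates),
                 expression_cpm_threshold = expression_cpm_threshold,
                 top_k = as.integer(top_k)),
            class = "iclip_config")
}

#' Per-gene coverage in RPKM
#'
#' Counts track events falling inside each gene and converts to reads per
#' kilobase per million: `events * 1e9 / (gene_length * library_size)`. Genes
#' with no events are reported with RPKM 0.
#'
#' @param track data.frame `chrom, pos, count` (0-based positions).
#' @param genes Gene annotation (`gene_id, chrom, start, end, length`).
#' @param library_size Total events in the library (must be positive).
#' @return data.frame `gene_id, events, rpkm`.
#' @export
coverage_per_gene <- function(track, genes, library_size) {
  if (library_size <= 0) stop("library_size must be positive")
  ev <- numeric(nrow(genes))
  if (nrow(track) > 0) {
    q <- GenomicRanges::GRanges(track$chrom,
                                IRanges::IRanges(track$pos + 1L, track$pos + 1L))
    s <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1L, genes$end))
    hits <- quiet_overlaps(q, s)
    if (length(hits)) {
      agg <- tapply(track$count[queryHits(hits)], subjectHits(hits), sum)
      ev[as.integer(names(agg))] <- agg
    }
  }
  data.frame(gene_id = genes$gene_id, events = ev,
             rpkm = ev * 1e9 / (genes$length * library_size),
             stringsAsFactors = FALSE)
}

#' Build the per-gene iCLIP/RNA-seq coverage table
#'
#' Combines iCLIP RPKM with RNA-seq RPKM (from expression counts) and the
#' log2 enrichment, which is defined only where both RPKMs are positive.
#'
#' @param iclip_track Pooled iCLIP event track.
#' @param expression data.frame `gene_id, count` of RNA-seq counts.
#' @param genes Gene annotation.
#' @param iclip_library_size Total iCLIP events (defaults to the track sum).
#' @return data.frame `gene_id, biotype, iclip_rpkm, rnaseq_rpkm, enrichment`.
#' @export
gene_coverage_table <- function(iclip_track, expression, genes,
                                iclip_library_size = sum(iclip_track$count)) {
  ic <- coverage_per_gene(iclip_track, genes, iclip_library_size)
  cnt <- expression$count[match(genes$gene_id, expression$gene_id)]
  rlib <- sum(expression$count)
  rk <- cnt * 1e9 / (genes$length * rlib)
  enr <- ifelse(ic$rpkm > 0 & rk > 0, log2(ic$rpkm / rk), NA)
  data.frame(gene_id = genes$gene_id, biotype = genes$biotype,
             iclip_rpkm = ic$rpkm, iclip_events = ic$events,
             rnaseq_count = cnt, rnaseq_rpkm = rk, enrichment = enr,
             stringsAsFactors = FALSE)
}

#' Per-biotype iCLIP enrichment distributions
#'
#' Splits the log2(iCLIP RPKM / RNA-seq RPKM) enrichment by RNA class and
#' summarizes each class with five-number statistics. Genes with undefined
#' enrichment are excluded; classes with no valid gene are omitted with a
#' warning.
#'
#' @param coverages Output of [gene_coverage_table()].
#' @return List: `values` (per-gene data.frame) and `summary` (per-biotype
#'   `min, q1, median, q3, max, n`).
#' @export
class_enrichment <- function(coverages) {
  ok <- !is.na(coverages$enrichment)
  empty <- setdiff(unique(coverages$biotype), unique(coverages$biotype[ok]))
  if (length(empty))
    warning("no genes with defined enrichment in class: ",
            paste(empty, collapse = ", "))
  vals <- coverages[ok, c("gene_id", "biotype", "enrichment")]
  sm <- do.call(rbind, lapply(split(vals$enrichment, vals$biotype), function(x) {
    f <- stats::fivenum(x)
    data.frame(min = f[1], q1 = f[2], median = f[3], q3 = f[4], max = f[5],
               n = length(x))
  }))
  sm <- data.frame(biotype = rownames(sm), sm, row.names = NULL,
                   stringsAsFactors = FALSE)
  list(values = vals, summary = sm)
}

#' Call reproducible fixed-width binding sites from crosslink tracks
#'
#' Implements the four-rule procedure: (1) drop the globally lowest scored
#' fraction of crosslink positions; (2) greedily seed sites at the remaining
#' positions in descending score order (ties by coordinate), extending each
#' seed symmetrically to `site_width` and suppressing candidates overlapping
#' an accepted site; (3) keep sites with at least `min_covered_positions`
#' event-covered positions in the pooled track; (4) keep sites with events in
#' at least `min_replicate_support` replicates.
#'
#' @param scores Pooled per-position score track (`chrom, pos, score`).
#' @param replicates List of per-replicate event tracks (`chrom, pos, count`).
#' @param cfg An [iclip_config()].
#' @param genes Optional annotation; adds a `gene_id` column (longest-overlap
#'   assignment).
#' @return data.frame `chrom, start, end, score, covered_positions,
#'   replicate_support[, gene_id]` of non-overlapping width-`site_width` sites.
#' @export
call_binding_sites <- function(scores, replicates, cfg = iclip_config(),
                               genes = NULL) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      score = numeric(), covered_positions = integer(),
                      replicate_support = integer(), stringsAsFactors = FALSE)
  if (is.null(scores) || nrow(scores) == 0) return(empty)
  flank <- (cfg$site_width - 1L) %/% 2L

  # (1) global score filter: drop the lowest fraction, ties resolved by
  # coordinate order so the cut is deterministic.
  o <- order(scores$score, scores$chrom, scores$pos)
  n_drop <- floor(cfg$score_percentile_drop * nrow(scores))
  keep <- scores[setdiff(o, o[seq_len(n_drop)]), ]

  pooled <- aggregate(count ~ chrom + pos,
                      data = do.call(rbind, replicates), FUN = sum)
  pos_by_chrom <- lapply(split(pooled$pos, pooled$chrom), sort)
  rep_pos <- lapply(replicates, function(r) lapply(split(r$pos, r$chrom), sort))
  count_in <- function(sorted, lo, hi) {
    if (is.null(sorted)) return(0L)
    findInterval(hi + 0.5, sorted) - findInterval(lo - 0.5, sorted)
  }

  # (2) greedy seeding in descending score order, suppression by overlap.
  cand <- keep[order(-keep$score, keep$chrom, keep$pos), ]
  acc_chrom <- character(0); acc_ctr <- integer(0)
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    same <- acc_ctr[acc_chrom == cand$chrom[i]]
    if (length(same) && any(abs(same - cand$pos[i]) < cfg$site_width)) next
    sel[i] <- TRUE
    acc_chrom <- c(acc_chrom, cand$chrom[i])
    acc_ctr <- c(acc_ctr, cand$pos[i])
  }
  sites <- cand[sel, , drop = FALSE]
  if (!nrow(sites)) return(empty)
  sites$start <- sites$pos - flank
  sites$end <- sites$pos + flank + 1L

  # (3) pooled coverage and (4) replicate support within each site.
  sites$covered_positions <- mapply(function(cn, lo, hi)
    count_in(pos_by_chrom[[cn]], lo, hi),
    sites$chrom, sites$start, sites$end - 1L)
  sites$replicate_support <- mapply(function(cn, lo, hi)
    sum(vapply(rep_pos, function(rp) count_in(rp[[cn]], lo, hi) > 0L, TRUE)),
    sites$chrom, sites$start, sites$end - 1L)
  sites <- sites[sites$covered_positions >= cfg$min_covered_positions &
                   sites$replicate_support >= cfg$min_replicate_support, ,
                 drop = FALSE]
  sites <- sites[order(sites$chrom, sites$start),
                 c("chrom", "start", "end", "score",
                   "covered_positions", "replicate_support")]
  rownames(sites) <- NULL
  if (!is.null(genes) && nrow(sites))
    sites$gene_id <- gene_of_interval(sites$chrom, sites$start,
                                      sites$end - sites$start, genes)
  sites
}

#' Observed versus expected binding sites per RNA biotype
#'
#' The expected distribution of binding sites over biotypes follows each
#' biotype's share of the expressed-gene universe (genes with CPM above the
#' configured threshold). For each biotype a 2x2 table of (in-biotype vs not)
#' x (observed vs expected-scaled) site counts is tested with a two-sided
#' Fisher exact test.
#'
#' @param sites Binding sites with a `gene_id` column.
#' @param expression data.frame `gene_id, count`.
#' @param genes Gene annotation with biotypes.
#' @param cfg An [iclip_config()].
#' @return data.frame `biotype, n_genes_expressed, observed, expected,
#'   odds_ratio, p_value`.
#' @export
biotype_site_enrichment <- function(sites, expression, genes,
                                    cfg = iclip_config()) {
  if (sum(expression$count) <= 0) stop("no expressed genes: empty library")
  cpm <- expression$count * 1e6 / sum(expression$count)
  universe <- expression$gene_id[cpm > cfg$expression_cpm_threshold]
  if (!length(universe)) stop("no expressed genes above the CPM threshold")
  ubio <- genes$biotype[match(universe, genes$gene_id)]
  insites <- sites[!is.na(sites$gene_id) & sites$gene_id %in% universe, ]
  total <- nrow(insites)
  res <- lapply(sort(unique(ubio)), function(b) {
    obs <- sum(genes$biotype[match(insites$gene_id, genes$gene_id)] == b)
    expn <- round(total * mean(ubio == b))
    ft <- fisher.test(matrix(c(obs, total - obs, expn, total - expn), nrow = 2))
    data.frame(biotype = b, n_genes_expressed = sum(ubio == b),
               observed = obs, expected = expn,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rank candidate lncRNAs by a mean scaled score
#'
#' Candidates are lncRNAs passing all upstream presence flags (seen in the
#' contact data, at least one binding site, expressed). Four metrics (iCLIP
#' coverage RPKM, expression RPKM, log2 enrichment, number of binding sites)
#' are each z-standardized against the full lncRNA universe; the composite is
#' their unweighted mean, candidates are sorted descending and the top `top_k`
#' selected.
#'
#' @param metrics data.frame over the lncRNA universe: `gene_id,
#'   iclip_coverage, expression, enrichment, n_binding_sites, presence`
#'   (logical).
#' @param cfg An [iclip_config()].
#' @return List: `ranked` (candidates with scaled metrics, composite, dense
#'   rank) and `top` (the selection). Warns when fewer than `top_k` candidates
#'   exist.
#' @export
stratify_candidates <- function(metrics, cfg = iclip_config()) {
  zs <- function(x) {
    mu <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(x)))
    z <- (x - mu) / s
    z[is.na(z)] <- 0
    z
  }
  sc <- data.frame(gene_id = metrics$gene_id,
                   z_iclip = zs(metrics$iclip_coverage),
                   z_expression = zs(metrics$expression),
                   z_enrichment = zs(metrics$enrichment),
                   z_sites = zs(metrics$n_binding_sites),
                   stringsAsFactors = FALSE)
  sc$composite <- rowMeans(sc[, c("z_iclip", "z_expression",
                                  "z_enrichment", "z_sites")])
  ranked <- sc[metrics$presence, , drop = FALSE]
  ranked <- ranked[order(-ranked$composite, ranked$gene_id), , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  if (nrow(ranked) < cfg$top_k)
    warning("only ", nrow(ranked), " candidates pass the presence screen; ",
            "returning all")
  list(ranked = ranked, top = head(ranked, cfg$top_k))
}
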