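#' Integration configuration
#'
#' @param abc_threshold Activity-by-contact score above which (strictly) an
#'   element-gene link is kept.
#' @param hic_resolution Contact-map resolution in bp (bookkeeping; contact
#'   values are consumed pre-binned at this resolution).
#' @param candidate_window Window around a gene's TSS, in bp, defining its
#'   candidate element universe (the ABC denominator).
#' @param deg_abs_log2fc,deg_padj,deg_min_mean Differential-expression
#'   thresholds: minimum absolute log2 fold change, maximum BH-adjusted p,
#'   minimum combined mean reads.
#' @return An `integration_config` list.
#' @export
integration_config <- function(abc_threshold = 0.02, hic_resolution = 1000L,
                               candidate_window = 5e6, deg_abs_log2fc = 0.59,
                               deg_padj = 0.05, deg_min_mean = 5) {
  if (abc_threshold <= 0 || abc_threshold >= 1)
    stop("abc_threshold must be in (0, 1)")
  if (candidate_window <= 0 || deg_abs_log2fc <= 0 || deg_padj <= 0 ||
      deg_min_mean <= 0)
    stop("thresholds must be positive")
  structure(list(abc_threshold = abc_threshold,
                 hic_resolution = as.integer(hic_resolution),
                 candidate_window = candidate_window,
                 deg_abs_log2fc = deg_abs_log2fc,
                 deg_padj = deg_padj,
                 deg_min_mean = deg_min_mean),
            class = "integration_config")
}

#' Activity-by-contact enhancer-gene links
#'
#' For each gene, candidate elements are those with a contact entry to the
#' gene lying within `candidate_window` of its TSS on the same chromosome.
#' The ABC score of element e for gene g is `A_e * C_eg / sum(A_e' * C_e'g)`
#' over the candidate universe, so scores sum to 1 per gene; links with a
#' score strictly above `abc_threshold` are returned. Genes with a zero
#' denominator yield no links.
#'
#' @param elements data.frame `element_id, chrom, start, end, activity`.
#' @param contacts data.frame `element_id, gene_id, contact`.
#' @param genes Gene annotation with `tss`.
#' @param cfg An [integration_config()].
#' @param apply_threshold If FALSE, return all scored links (used by
#'   conservation checks).
#' @return data.frame `element_id, gene_id, activity, contact, abc`.
#' @export
compute_abc <- function(elements, contacts, genes, cfg = integration_config(),
                        apply_threshold = TRUE) {
  stopifnot(all(contacts$contact >= 0))
  ei <- match(contacts$element_id, elements$element_id)
  if (anyNA(ei)) stop("contacts reference unknown elements")
  gi <- match(contacts$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("contacts reference unknown genes")
  act <- elements$activity[ei]
  if (any(act < 0)) stop("activities must be non-negative")
  mid <- (elements$start[ei] + elements$end[ei]) / 2
  in_win <- elements$chrom[ei] == genes$chrom[gi] &
    abs(mid - genes$tss[gi]) <= cfg$candidate_window
  d <- data.frame(element_id = contacts$element_id,
                  gene_id = contacts$gene_id,
                  activity = act, contact = contacts$contact,
                  stringsAsFactors = FALSE)[in_win, , drop = FALSE]
  d$ac <- d$activity * d$contact
  denom <- tapply(d$ac, d$gene_id, sum)
  d$abc <- d$ac / as.numeric(denom[d$gene_id])
  d <- d[!is.na(d$abc) & denom[d$gene_id] > 0, , drop = FALSE]
  d$ac <- NULL
  rownames(d) <- NULL
  if (apply_threshold) d <- d[d$abc > cfg$abc_threshold, , drop = FALSE]
  d
}

#' Apply differential-expression thresholds to a statistics table
#'
#' A gene is a DEG iff `|log2fc| >= deg_abs_log2fc`, `padj <= deg_padj` and
#' `base_mean >= deg_min_mean`. Genes with missing adjusted p-values are
#' excluded with a warning.
#'
#' @param stats data.frame `gene_id, log2fc, padj, base_mean` (a `pvalue`
#'   column may be present and is ignored).
#' @param cfg An [integration_config()].
#' @return The table with `is_deg` and `direction` (`up`/`down`/`none`)
#'   columns.
#' @export
filter_degs <- function(stats, cfg = integration_config()) {
  if (anyNA(stats$padj)) {
    warning(sum(is.na(stats$padj)), " genes without adjusted p-value excluded")
    stats <- stats[!is.na(stats$padj), , drop = FALSE]
  }
  stats$is_deg <- abs(stats$log2fc) >= cfg$deg_abs_log2fc &
    stats$padj <= cfg$deg_padj & stats$base_mean >= cfg$deg_min_mean
  stats$direction <- ifelse(!stats$is_deg, "none",
                            ifelse(stats$log2fc > 0, "up", "down"))
  stats
}

#' Exclusive intersection counts over lost-enhancer sets
#'
#' Tallies, for every non-empty exclusive membership pattern over the named
#' sets, the number of elements with exactly that pattern (the counts behind
#' an upset plot). Pattern counts sum to the size of the union.
#'
#' @param sets Named list of id vectors.
#' @return data.frame `pattern` (set names joined by `&`), `degree`, `count`.
#' @export
lost_enhancer_overlap <- function(sets) {
  stopifnot(length(names(sets)) == length(sets))
  univ <- unique(unlist(sets, use.names = FALSE))
  if (!length(univ))
    return(data.frame(pattern = character(), degree = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  member <- matrix(member, nrow = length(univ),
                   dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  tb <- table(pat)
  data.frame(pattern = names(tb),
             degree = lengths(strsplit(names(tb), "&", fixed = TRUE)),
             count = as.integer(tb), stringsAsFactors = FALSE)
}

#' Fraction of PROTAC-lost enhancers attributable to lncRNA knockdowns
#'
#' @param protac_lost Ids of enhancers lost after PROTAC (non-empty).
#' @param knockdown_lost Named list of per-knockdown lost-enhancer id sets.
#' @return List with `n_protac`, `n_knockdown_union`, `n_both` and
#'   `fraction = |protac inter union| / |protac|`.
#' @export
protac_attribution <- function(protac_lost, knockdown_lost) {
  protac_lost <- unique(protac_lost)
  if (!length(protac_lost)) stop("empty PROTAC lost set: fraction undefined")
  u <- unique(unlist(knockdown_lost, use.names = FALSE))
  both <- intersect(protac_lost, u)
  list(n_protac = length(protac_lost), n_knockdown_union = length(u),
       n_both = length(both), fraction = length(both) / length(protac_lost))
}

#' DEG-promoter degree of lost enhancers
#'
#' For each lost enhancer, its hub degree is the number of linked genes
#' flagged as DEGs; returns the degree per enhancer, the degree histogram,
#' and the union of DEGs reachable from the lost set.
#'
#' @param lost Ids of lost enhancers.
#' @param links Thresholded link table from [compute_abc()].
#' @param degs Character vector of DEG gene ids.
#' @return List: `degree` (named integer per lost enhancer), `histogram`
#'   (data.frame `degree, n_enhancers`), `linked_degs`.
#' @export
hub_degree <- function(lost, links, degs) {
  lost <- unique(lost)
  if (!length(lost))
    return(list(degree = setNames(integer(0), character(0)),
                histogram = data.frame(degree = integer(), n_enhancers = integer()),
                linked_degs = character(0)))
  lk <- links[links$element_id %in% lost & links$gene_id %in% degs, ,
              drop = FALSE]
  lk <- unique(lk[, c("element_id", "gene_id")])
  deg <- setNames(integer(length(lost)), lost)
  if (nrow(lk)) {
    tb <- table(lk$element_id)
    deg[names(tb)] <- as.integer(tb)
  }
  hist <- as.data.frame(table(degree = deg), stringsAsFactors = FALSE)
  names(hist) <- c("degree", "n_enhancers")
  hist$degree <- as.integer(hist$degree)
  list(degree = deg, histogram = hist,
       linked_degs = sort(unique(lk$gene_id)))
}

#' Concordance between one perturbation's lost enhancers and another's DEGs
#'
#' Intersects the genes linked to the first perturbation's lost enhancers
#' with the second perturbation's DEG set (Venn-style counts).
#'
#' @param lost_a Lost-enhancer ids of perturbation A.
#' @param links Thresholded link table.
#' @param degs_b DEG gene ids of perturbation B.
#' @return List: `linked_genes`, `overlap`, and counts `n_linked_only`,
#'   `n_deg_only`, `n_both`.
#' @export
perturbation_concordance <- function(lost_a, links, degs_b) {
  linked <- sort(unique(links$gene_id[links$element_id %in% lost_a]))
  both <- intersect(linked, degs_b)
  list(linked_genes = linked, overlap = both,
       n_linked_only = length(setdiff(linked, degs_b)),
       n_deg_only = length(setdiff(degs_b, linked)),
       n_both = length(both))
}
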