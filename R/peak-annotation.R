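#' Peak annotation configuration
#'
#' @param promoter_upstream,promoter_downstream Promoter window half-widths in
#'   bp around the TSS (strand-aware: upstream is 5' of the TSS).
#' @return An `annotation_config` list.
#' @export
annotation_config <- function(promoter_upstream = 1000L,
                              promoter_downstream = 100L) {
  if (promoter_upstream < 0 || promoter_downstream < 0)
    stop("promoter window sizes must be non-negative")
  structure(list(promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream)),
            class = "annotation_config")
}

#' Genomic-context annotation of peaks
#'
#' The peak midpoint decides a single label so the three contexts partition
#' any peak set: `promoter` if the midpoint falls in a strand-aware window
#' around any TSS, else `intronic` if it falls inside a gene body, else
#' `intergenic`.
#'
#' @param peaks data.frame `chrom, start, end` (0-based half-open).
#' @param genes Gene annotation with `tss` and `strand`.
#' @param cfg An [annotation_config()].
#' @return Character vector of context labels, one per peak.
#' @export
annotate_context <- function(peaks, genes, cfg = annotation_config()) {
  mid <- (peaks$start + peaks$end) %/% 2L
  q <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  plus <- genes$strand == "+"
  ps <- ifelse(plus, genes$tss - cfg$promoter_upstream,
               genes$tss - cfg$promoter_downstream)
  pe <- ifelse(plus, genes$tss + cfg$promoter_downstream,
               genes$tss + cfg$promoter_upstream)
  prom <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(ps, 0L) + 1L, pe + 1L))
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  in_prom <- quiet_count(q, prom) > 0L
  in_body <- quiet_count(q, body) > 0L
  ifelse(in_prom, "promoter", ifelse(in_body, "intronic", "intergenic"))
}

#' Assign a chromatin state to each peak
#'
#' The state with the largest base-pair overlap wins; ties are resolved by
#' the state at the peak midpoint. Peaks outside the segmentation are
#' `"unannotated"`.
#'
#' @param peaks data.frame `chrom, start, end`.
#' @param segmentation data.frame `chrom, start, end, state` tiling intervals.
#' @return Character vector of state labels.
#' @export
assign_state <- function(peaks, segmentation) {
  q <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1L, peaks$end))
  s <- GenomicRanges::GRanges(segmentation$chrom,
                              IRanges::IRanges(segmentation$start + 1L,
                                               segmentation$end))
  hits <- quiet_overlaps(q, s)
  out <- rep("unannotated", nrow(peaks))
  if (!length(hits)) return(out)
  w <- IRanges::width(IRanges::pintersect(q[queryHits(hits)], s[subjectHits(hits)]))
  st <- segmentation$state[subjectHits(hits)]
  bp <- tapply(w, list(queryHits(hits), st), sum, default = 0)
  for (r in seq_len(nrow(bp))) {
    qi <- as.integer(rownames(bp)[r])
    best <- which(bp[r, ] == max(bp[r, ]))
    if (length(best) == 1L) {
      out[qi] <- colnames(bp)[best]
    } else {
      mid <- (peaks$start[qi] + peaks$end[qi]) %/% 2L
      j <- which(segmentation$chrom == peaks$chrom[qi] &
                   segmentation$start <= mid & segmentation$end > mid)
      out[qi] <- if (length(j)) segmentation$state[j[1]] else colnames(bp)[best[1]]
    }
  }
  out
}

#' Classify peaks by the RNA class of their overlapping contacts
#'
#' A contact is "at" a peak if its DNA bin overlaps the peak by any amount.
#' A peak is `none` with no overlapping contact, `trans` if all overlapping
#' contacts are trans, `cis` if all are cis, and `mixed` otherwise. Invariant
#' to the order of the contact table.
#'
#' @param peaks data.frame `peak_id, chrom, start, end`.
#' @param contacts Classified contact table (with `rna_class`).
#' @return data.frame `peak_id, rna_class` with levels
#'   `none|cis|trans|mixed`.
#' @export
classify_peak_rna_association <- function(peaks, contacts) {
  q <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1L, peaks$end))
  s <- GenomicRanges::GRanges(contacts$chrom,
                              IRanges::IRanges(contacts$start + 1L, contacts$end))
  hits <- quiet_overlaps(q, s)
  has_trans <- has_cis <- logical(nrow(peaks))
  cls <- contacts$rna_class[subjectHits(hits)]
  qh <- queryHits(hits)
  has_trans[unique(qh[cls == "trans"])] <- TRUE
  has_cis[unique(qh[cls == "cis"])] <- TRUE
  lab <- ifelse(!has_trans & !has_cis, "none",
                ifelse(has_trans & has_cis, "mixed",
                       ifelse(has_trans, "trans", "cis")))
  data.frame(peak_id = peaks$peak_id, rna_class = lab, stringsAsFactors = FALSE)
}

#' Cell-type specificity of genomic features
#'
#' A feature is specific to the target cell type iff its chromatin state
#' there belongs to the enhancer state set while its state in every other
#' cell type belongs to the repressed/inactive set; otherwise shared.
#' Features unannotated in the target cell are excluded (NA call).
#'
#' @param features data.frame `chrom, start, end` (plus optional ids).
#' @param segmentations Named list of segmentation data.frames, one per cell
#'   type.
#' @param target_cell Name of the target cell type in `segmentations`.
#' @param enhancer_states Character set of enhancer state labels.
#' @param inactive_states Character set of repressed/inactive state labels.
#' @return List: `state_matrix` (feature x cell data.frame of states) and
#'   `call` (`"specific"`/`"shared"`/NA per feature).
#' @export
cell_type_specificity <- function(features, segmentations, target_cell,
                                  enhancer_states, inactive_states) {
  if (length(segmentations) < 2L)
    stop("at least two cell-type segmentations are required")
  if (!target_cell %in% names(segmentations))
    stop("target_cell not among the segmentations")
  states <- vapply(segmentations, function(seg) assign_state(features, seg),
                   character(nrow(features)))
  states <- matrix(states, nrow = nrow(features),
                   dimnames = list(NULL, names(segmentations)))
  others <- setdiff(colnames(states), target_cell)
  tgt <- states[, target_cell]
  spec <- tgt %in% enhancer_states &
    apply(states[, others, drop = FALSE], 1,
          function(x) all(x %in% inactive_states))
  call <- ifelse(tgt == "unannotated", NA_character_,
                 ifelse(spec, "specific", "shared"))
  list(state_matrix = as.data.frame(states, stringsAsFactors = FALSE),
       call = call)
}
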