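#' Run the full analysis pipeline on a simulated dataset
#'
#' Chains every stage on the in-memory outputs of [simulate_dataset()]:
#' chimera extraction and unique alignment, binned contact assignment with
#' normalization and cis/trans classification, iCLIP binding-site calling and
#' candidate ranking, peak annotation (context, chromatin state, RNA class),
#' per-knockdown differential binding and the PROTAC pileup test, and
#' ABC-linked DEG/hub integration.
#'
#' @param sim A `triad_simulation` from [simulate_dataset()].
#' @param min_contact_count Minimum raw contact count for a (gene, bin) pair
#'   to enter the recovered trans-target set (separates planted signal from
#'   singleton background contacts).
#' @param enhancer_states,inactive_states Chromatin-state label sets used for
#'   specificity calls.
#' @return A list of per-stage results; see the pipeline vignette.
#' @export
run_pipeline <- function(sim, min_contact_count = 5L,
                         enhancer_states = "Strong_Enhancer",
                         inactive_states = c("Repressed", "Quiescent")) {
  cfg <- sim$config
  genes <- sim$ref$genes
  ccfg <- contact_config(bin_width = cfg$bin_width)

  parts <- extract_chimeras(sim$fastq$read1, sim$fastq$read2, sim$ref$genome,
                            id = sim$fastq$id)
  bins <- make_bins(sim$ref$chrom_sizes, ccfg)
  contacts <- assign_contacts(parts, genes, bins, ccfg)
  contacts <- normalize_contacts(contacts, ccfg)
  contacts <- classify_cis_trans(contacts, genes, ccfg)

  # Recovered guide -> target-bin calls: confident trans contacts.
  strong <- contacts[contacts$rna_class == "trans" &
                       contacts$raw_count >= min_contact_count, ]
  recovered_targets <- split(bin_id(strong$chrom, strong$start, strong$end),
                             strong$rna_gene_id)

  icfg <- iclip_config(n_replicates = cfg$n_iclip_replicates)
  sites <- call_binding_sites(sim$iclip$scores, sim$iclip$replicates, icfg,
                              genes = genes)
  pooled <- aggregate(count ~ chrom + pos, data = do.call(rbind, sim$iclip$replicates),
                      FUN = sum)
  cov <- gene_coverage_table(pooled, sim$iclip$expression, genes)
  enrich <- biotype_site_enrichment(sites, sim$iclip$expression, genes, icfg)

  lnc <- cov[cov$biotype == "lncRNA", ]
  cpm <- sim$iclip$expression$count * 1e6 / sum(sim$iclip$expression$count)
  expressed <- sim$iclip$expression$gene_id[cpm > icfg$expression_cpm_threshold]
  n_sites <- table(sites$gene_id)
  metrics <- data.frame(
    gene_id = lnc$gene_id,
    iclip_coverage = lnc$iclip_rpkm,
    expression = lnc$rnaseq_rpkm,
    enrichment = ifelse(is.na(lnc$enrichment), 0, lnc$enrichment),
    n_binding_sites = as.integer(n_sites[lnc$gene_id]),
    stringsAsFactors = FALSE)
  metrics$n_binding_sites[is.na(metrics$n_binding_sites)] <- 0L
  metrics$presence <- metrics$gene_id %in% contacts$rna_gene_id &
    metrics$n_binding_sites > 0L & metrics$gene_id %in% expressed
  candidates <- stratify_candidates(metrics, icfg)

  peaks <- sim$peaksets$peaks
  context <- annotate_context(peaks, genes)
  state <- assign_state(peaks, sim$segmentations[[1]])
  # RNA-association classes from the confident contact set: singleton
  # background contacts blanket every bin and carry no signal.
  rna_class <- classify_peak_rna_association(peaks, strong)
  peak_table <- data.frame(peaks, context = context, state = state,
                           rna_class = rna_class$rna_class,
                           stringsAsFactors = FALSE)
  peak_freq <- peak_overlap_frequencies(contacts, peaks)

  dcfg <- diff_config()
  counts <- sim$peaksets$counts
  peak_levels <- unique(counts$peak_id)
  wide <- function(cond) {
    d <- counts[counts$condition == cond, ]
    tapply(d$count, list(factor(d$peak_id, levels = peak_levels),
                         d$replicate), sum)
  }
  ctrl <- wide("control")
  kd_conditions <- setdiff(unique(counts$condition), "control")
  differential <- lapply(kd_conditions, function(cd) {
    m <- cbind(ctrl, wide(cd))
    test_differential(m, rep(c("control", cd), each = ncol(ctrl)), dcfg)
  })
  names(differential) <- kd_conditions
  enhancer_peaks <- peak_table$peak_id[peak_table$state %in% enhancer_states]
  lost_enhancers <- lapply(differential, function(d)
    intersect(d$peak_id[d$direction == "lost"], enhancer_peaks))

  atac <- sim$peaksets$atac
  lr <- poisson_loglr(atac$control, atac$protac,
                      sim$peaksets$atac_depths[["control"]],
                      sim$peaksets$atac_depths[["protac"]], dcfg)
  protac_lost <- intersect(atac$peak_id[lr$direction == "lost"], enhancer_peaks)

  igf <- integration_config()
  enh <- peaks[peaks$peak_id %in% sim$hic$activities$element_id, ]
  elements <- data.frame(enh[, c("peak_id", "chrom", "start", "end")],
                         activity = sim$hic$activities$activity[
                           match(enh$peak_id, sim$hic$activities$element_id)],
                         stringsAsFactors = FALSE)
  names(elements)[1] <- "element_id"
  links <- compute_abc(elements, sim$hic$contacts, genes, igf)
  degs <- lapply(sim$hic$deg_tables, filter_degs, cfg = igf)
  deg_sets <- lapply(degs, function(d) d$gene_id[d$is_deg])

  upset <- lost_enhancer_overlap(lost_enhancers)
  attribution <- protac_attribution(protac_lost, lost_enhancers)
  hubs <- hub_degree(protac_lost, links, deg_sets[["protac"]])
  kd_degs <- lapply(names(lost_enhancers), function(cd)
    hub_degree(lost_enhancers[[cd]], links, deg_sets[[cd]])$linked_degs)
  names(kd_degs) <- names(lost_enhancers)

  list(parts = parts, contacts = contacts,
       recovered_targets = recovered_targets,
       sites = sites, coverage = cov, biotype_enrichment = enrich,
       candidates = candidates, peak_table = peak_table,
       peak_freq = peak_freq,
       differential = differential, lost_enhancers = lost_enhancers,
       atac_loglr = cbind(atac["peak_id"], lr), protac_lost = protac_lost,
       links = links, degs = degs, upset = upset, attribution = attribution,
       hubs = hubs, knockdown_linked_degs = kd_degs)
}

#' Compare pipeline output with the planted ground truth
#'
#' Computes the recovery metrics used throughout the test-suite: recall and
#' precision of guide-to-target trans contacts, binding-site recall and
#' precision (exact 7-nt coordinates), the candidate ranks of the planted
#' guides, per-knockdown lost-enhancer recall, PROTAC-lost recall, and the
#' fraction of planted DEGs reachable through surviving links.
#'
#' @param res Output of [run_pipeline()].
#' @param truth The `ground_truth` manifest of the simulation.
#' @return A named list of scalar metrics.
#' @export
recovery_report <- function(res, truth) {
  true_pairs <- unlist(lapply(names(truth$guide_targets), function(g)
    paste(g, truth$guide_targets[[g]])), use.names = FALSE)
  rec_pairs <- unlist(lapply(names(res$recovered_targets), function(g)
    paste(g, res$recovered_targets[[g]])), use.names = FALSE)
  contact_recall <- mean(true_pairs %in% rec_pairs)
  contact_precision <- if (length(rec_pairs)) mean(rec_pairs %in% true_pairs) else NA

  ps <- truth$planted_binding_sites
  tkey <- paste(ps$chrom, ps$start)
  ckey <- paste(res$sites$chrom, res$sites$start)
  site_recall <- mean(tkey %in% ckey)
  site_precision <- if (length(ckey)) mean(ckey %in% tkey) else NA

  ranks <- res$candidates$ranked
  guide_ranks <- ranks$rank[match(truth$guides, ranks$gene_id)]
  guides_in_top <- sum(!is.na(guide_ranks) &
                         guide_ranks <= length(truth$guides))

  kd <- names(truth$knockdown_lost_peaks)
  lost_recall <- mean(unlist(lapply(kd, function(g) {
    truth$knockdown_lost_peaks[[g]] %in%
      res$lost_enhancers[[paste0("si_", g)]]
  })))
  protac_recall <- mean(truth$protac_lost_peaks %in% res$protac_lost)

  deg_recovery <- mean(unlist(lapply(kd, function(g) {
    truth$planted_degs[[paste0("si_", g)]] %in%
      res$knockdown_linked_degs[[paste0("si_", g)]]
  })))

  list(contact_recall = contact_recall,
       contact_precision = contact_precision,
       site_recall = site_recall,
       site_precision = site_precision,
       guides_in_top = guides_in_top,
       lost_enhancer_recall = lost_recall,
       protac_lost_recall = protac_recall,
       deg_recovery = deg_recovery,
       attribution_fraction = res$attribution$fraction)
}
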