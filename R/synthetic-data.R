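#' Synthetic multi-omic dataset with planted ground truth
#'
#' The generator family below builds a miniature genome plus every input the
#' pipeline consumes: bridge-adapter chimeric reads for planted guide lncRNAs
#' contacting distal enhancer bins, per-nucleotide iCLIP crosslink tracks over
#' replicates with planted 7-nt binding sites, knockdown/PROTAC peak count
#' matrices, loop and differential-expression tables, and chromatin-state
#' segmentations for several cell types. All coordinates are 0-based
#' half-open. Every generator draws from its own RNG stream (`seed + offset`)
#' and is byte-deterministic under a fixed config.
#'
#' @name synthetic_data
NULL

# Bridge adapter used by the proximity-ligation protocol this package models.
BRIDGE_SEQUENCE <- "AGTCGGAGCGTTGCCTATCGCATTGATGGTGCTAGGA"

# Vectorized extraction of genome fragments (0-based half-open coordinates).
extract_genome <- function(genome, chrom, start0, width) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    frs <- Biostrings::extractAt(genome[[cn]],
                                 IRanges::IRanges(start = start0[i] + 1L,
                                                  width = width[i]))
    out[i] <- as.character(frs)
  }
  out
}

#' Generate the synthetic reference genome and gene annotation
#'
#' Places non-overlapping genes with strand, biotype and TSS on random-sequence
#' chromosomes. Chromosome sequences are guaranteed to contain no copy of the
#' bridge adapter (either orientation), so bridge detection in reads is
#' unambiguous.
#'
#' @param config A [synthetic_config()].
#' @return A list with `genome` (a [Biostrings::DNAStringSet]), `chrom_sizes`
#'   (named integer vector) and `genes` (data.frame with `gene_id, chrom,
#'   start, end, strand, biotype, tss, length`).
#' @export
generate_reference <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed + .rng_offsets[["reference"]], {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    seqs <- vapply(chroms, function(cn) random_dna(config$chromosome_length), "")
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms
    genome <- scrub_bridge(genome)

    # Even split of genes across chromosomes; each gene gets its own slot so
    # placement is non-overlapping by construction.
    per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
    lens <- sample(1000:4000, config$n_genes, replace = TRUE)
    max_len <- 4000L
    rows <- vector("list", config$n_chromosomes)
    k <- 0L
    for (ci in seq_along(chroms)) {
      ng <- per_chrom[ci]
      if (ng == 0L) next
      slot <- config$chromosome_length %/% ng
      if (slot < max_len + 200L)
        stop("genome too small to place ", config$n_genes,
             " non-overlapping genes; reduce n_genes or enlarge chromosomes")
      gl <- lens[k + seq_len(ng)]
      offs <- floor(runif(ng) * (slot - gl - 100L))
      start <- (seq_len(ng) - 1L) * slot + offs
      rows[[ci]] <- data.frame(chrom = chroms[ci], start = start,
                               end = start + gl, stringsAsFactors = FALSE)
      k <- k + ng
    }
    genes <- do.call(rbind, rows)
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$biotype <- assign_biotypes(config$biotype_fractions, nrow(genes))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    genes$length <- genes$end - genes$start
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand",
                       "biotype", "tss", "length")]
    rownames(genes) <- NULL
    list(genome = genome,
         chrom_sizes = setNames(rep(config$chromosome_length, length(chroms)), chroms),
         genes = genes)
  })
}

# Replace any accidental bridge occurrence (either orientation) with a point
# substitution until none remain; astronomically rare on random sequence.
scrub_bridge <- function(genome) {
  pats <- c(BRIDGE_SEQUENCE, revcomp(BRIDGE_SEQUENCE))
  repeat {
    hit <- FALSE
    for (cn in names(genome)) for (p in pats) {
      m <- Biostrings::matchPattern(p, genome[[cn]])
      if (length(m) > 0) {
        hit <- TRUE
        pos <- IRanges::start(m)[1]
        base <- as.character(Biostrings::subseq(genome[[cn]], pos, pos))
        alt <- setdiff(c("A", "C", "G", "T"), base)[1]
        Biostrings::subseq(genome[[cn]], pos, pos) <- Biostrings::DNAString(alt)
      }
    }
    if (!hit) return(genome)
  }
}

# Largest-remainder apportionment of biotype counts, then a random assignment.
assign_biotypes <- function(fractions, n) {
  cnt <- floor(fractions * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(fractions * n - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  sample(rep(names(fractions), times = cnt))
}

#' Plant the ground truth: guides, targets, peaks, sites, loops and DEGs
#'
#' Chooses the guide lncRNAs, their distal (>5 Mb or interchromosomal) target
#' enhancer bins, the consensus peak set (target enhancers, PROTAC-only
#' enhancers, promoter and intergenic background peaks), the planted 7-nt
#' binding sites, the enhancer-to-promoter loop table, and the per-condition
#' planted DEG sets. The returned manifest is the oracle for every recovery
#' test downstream.
#'
#' @param config A [synthetic_config()].
#' @param ref Output of [generate_reference()].
#' @return A `ground_truth` list; see fields in the source.
#' @export
plant_truth <- function(config, ref) {
  with_seed(config$seed + .rng_offsets[["truth"]], {
    genes <- ref$genes
    bins <- make_bins(ref$chrom_sizes, contact_config(bin_width = config$bin_width))
    full <- bins[bins$end - bins$start == config$bin_width, ]

    # Bins overlapping no gene are eligible enhancer loci.
    gr_bins <- GenomicRanges::GRanges(full$chrom, IRanges::IRanges(full$start + 1, full$end))
    gr_genes <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
    genefree <- full[GenomicRanges::countOverlaps(gr_bins, gr_genes) == 0L, ]

    lnc <- genes[genes$biotype == "lncRNA" & genes$length >= 1500, ]
    if (nrow(lnc) < config$n_guides + config$n_decoy_binders)
      stop("not enough lncRNA genes to plant guides and decoy binders")
    pick <- sample(nrow(lnc), config$n_guides + config$n_decoy_binders)
    guides <- lnc$gene_id[pick[seq_len(config$n_guides)]]
    decoys <- lnc$gene_id[pick[-seq_len(config$n_guides)]]

    guide_targets <- list()
    for (g in guides) {
      row <- genes[genes$gene_id == g, ]
      othr <- genefree$chrom != row$chrom
      gap <- pmax(genefree$start - row$end, row$start - genefree$end, 0L)
      ok <- othr | gap > 5e6
      cand <- genefree[ok, ]
      if (nrow(cand) < config$targets_per_guide)
        stop("not enough distal gene-free bins for guide ", g)
      sel <- cand[sample(nrow(cand), config$targets_per_guide), ]
      guide_targets[[g]] <- bin_id(sel$chrom, sel$start, sel$end)
    }

    target_bins <- unique(unlist(guide_targets, use.names = FALSE))
    used <- match(target_bins, bin_id(genefree$chrom, genefree$start, genefree$end))
    enh_target <- data.frame(peak_id = paste0("enh_", gsub("[:-]", "_", target_bins)),
                             chrom = genefree$chrom[used],
                             start = genefree$start[used],
                             end = genefree$end[used],
                             kind = "target_enhancer",
                             stringsAsFactors = FALSE)

    pool <- genefree[-used, ]
    if (nrow(pool) < config$n_protac_only_enhancers + config$n_background_peaks %/% 2)
      stop("not enough gene-free bins for background peak placement")
    sel <- sample(nrow(pool), config$n_protac_only_enhancers)
    po <- pool[sel, ]
    enh_protac <- data.frame(peak_id = paste0("enh_", gsub("[:-]", "_",
                                bin_id(po$chrom, po$start, po$end))),
                             chrom = po$chrom, start = po$start, end = po$end,
                             kind = "protac_enhancer", stringsAsFactors = FALSE)
    pool <- pool[-sel, ]

    # Stable background peaks: half promoter-proximal, half intergenic.
    n_prom <- config$n_background_peaks %/% 2
    pg <- genes[sample(nrow(genes), n_prom), ]
    prom <- data.frame(peak_id = sprintf("peak_prom_%04d", seq_len(n_prom)),
                       chrom = pg$chrom,
                       start = pmax(pg$tss - 500L, 0L),
                       end = pg$tss + 500L,
                       kind = "promoter_peak", stringsAsFactors = FALSE)
    n_oth <- config$n_background_peaks - n_prom
    ob <- pool[sample(nrow(pool), n_oth), ]
    ctr <- ob$start + config$bin_width %/% 2L
    othp <- data.frame(peak_id = sprintf("peak_bg_%04d", seq_len(n_oth)),
                       chrom = ob$chrom, start = ctr - 500L, end = ctr + 500L,
                       kind = "background_peak", stringsAsFactors = FALSE)
    peaks <- rbind(enh_target, enh_protac, prom, othp)
    rownames(peaks) <- NULL

    target_peak_id <- setNames(enh_target$peak_id,
                               bin_id(enh_target$chrom, enh_target$start, enh_target$end))
    knockdown_lost_peaks <- lapply(guide_targets, function(b)
      unname(target_peak_id[b]))
    protac_lost_peaks <- c(enh_target$peak_id, enh_protac$peak_id)

    # Planted 7-nt binding sites: many per guide, a few per decoy lncRNA.
    site_rows <- list()
    plant_sites <- function(gid, n_sites) {
      row <- genes[genes$gene_id == gid, ]
      grid <- seq(row$start + 10L, row$end - 10L, by = 25L)
      ctr <- sort(sample(grid, min(n_sites, length(grid))))
      data.frame(gene_id = gid, chrom = row$chrom, start = ctr - 3L,
                 end = ctr + 4L, strand = row$strand, stringsAsFactors = FALSE)
    }
    for (g in guides) site_rows[[g]] <- plant_sites(g, config$sites_per_guide)
    for (d in decoys) site_rows[[d]] <- plant_sites(d, sample(1:3, 1))
    planted_binding_sites <- do.call(rbind, site_rows)
    rownames(planted_binding_sites) <- NULL

    # Loop table: every lost enhancer loops to 1-5 protein-coding promoters on
    # its own chromosome within 5 Mb (Hi-C contacts are short-range, and the
    # activity-by-contact candidate window is +/-5 Mb of the TSS).
    pc <- genes[genes$biotype == "protein_coding", ]
    lost_universe <- protac_lost_peaks
    deg_rng <- config$loops_per_enhancer
    pk <- peaks[match(lost_universe, peaks$peak_id), ]
    mid <- (pk$start + pk$end) / 2
    loop_rows <- lapply(seq_along(lost_universe), function(i) {
      near <- pc$gene_id[pc$chrom == pk$chrom[i] & abs(pc$tss - mid[i]) <= 4.9e6]
      if (!length(near)) return(NULL)
      d <- sample(seq(deg_rng[1], deg_rng[2]), 1)
      data.frame(enhancer_id = lost_universe[i],
                 gene_id = sample(near, min(d, length(near))),
                 stringsAsFactors = FALSE)
    })
    loop_table <- do.call(rbind, loop_rows)
    rownames(loop_table) <- NULL

    kd_conditions <- paste0("si_", guides)
    planted_degs <- setNames(lapply(guides, function(g) {
      sort(unique(loop_table$gene_id[loop_table$enhancer_id %in%
                                       knockdown_lost_peaks[[g]]]))
    }), kd_conditions)
    planted_degs$protac <- sort(unique(loop_table$gene_id))

    structure(list(guides = guides,
                   decoy_binders = decoys,
                   guide_targets = guide_targets,
                   peaks = peaks,
                   knockdown_lost_peaks = knockdown_lost_peaks,
                   protac_lost_peaks = protac_lost_peaks,
                   planted_binding_sites = planted_binding_sites,
                   loop_table = loop_table,
                   planted_degs = planted_degs),
              class = "ground_truth")
  })
}
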