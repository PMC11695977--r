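#' Generate bridge-adapter chimeric read pairs
#'
#' Each signal pair is a 100-nt chimeric read (DNA fragment from one of the
#' guide's planted target bins + bridge copy with substitutions at
#' `bridge_mutation_rate` + RNA fragment from the guide gene) with an RNA
#' 3'-end mate from the same gene whose transcript sequence starts with `GGG`
#' (so it passes 3'-RNA validation and still aligns exactly). Background pairs
#' couple a random gene with a random bin. Half the chimeric reads are emitted
#' reverse-complemented to exercise the reverse bridge orientation.
#'
#' @param config A [synthetic_config()].
#' @param ref Output of [generate_reference()].
#' @param truth Output of [plant_truth()].
#' @return A list with `read1`, `read2` (character vectors), `id`, and an
#'   `info` data.frame recording which reads are signal and their true loci.
#' @export
generate_chimeric_fastq <- function(config, ref, truth) {
  with_seed(config$seed + .rng_offsets[["fastq"]], {
    genes <- ref$genes
    n <- config$n_contacts
    bins <- make_bins(ref$chrom_sizes, contact_config(bin_width = config$bin_width))
    full <- bins[bins$end - bins$start == config$bin_width, ]

    is_bg <- runif(n) < config$background_contact_fraction
    gene_id <- character(n)
    b_chrom <- character(n); b_start <- integer(n)

    sig <- which(!is_bg)
    gsel <- sample.int(length(truth$guides), length(sig), replace = TRUE)
    gene_id[sig] <- truth$guides[gsel]
    for (gi in seq_along(truth$guides)) {
      j <- sig[gsel == gi]
      picks <- sample(truth$guide_targets[[gi]], length(j), replace = TRUE)
      pp <- parse_bin_id(picks)
      b_chrom[j] <- pp$chrom; b_start[j] <- pp$start
    }
    bg <- which(is_bg)
    gene_id[bg] <- sample(genes$gene_id, length(bg), replace = TRUE)
    bsel <- sample.int(nrow(full), length(bg), replace = TRUE)
    b_chrom[bg] <- full$chrom[bsel]; b_start[bg] <- full$start[bsel]

    gi <- match(gene_id, genes$gene_id)
    dna_len <- sample(20:43, n, replace = TRUE)
    rna_len <- 100L - 37L - dna_len
    dna_start <- b_start + floor(runif(n) * (config$bin_width - dna_len + 1L))
    dna_seq <- extract_genome(ref$genome, b_chrom, dna_start, dna_len)

    rna_off <- floor(runif(n) * (genes$length[gi] - rna_len + 1L))
    rna_start <- genes$start[gi] + rna_off
    rna_seq <- extract_genome(ref$genome, genes$chrom[gi], rna_start, rna_len)
    minus <- genes$strand[gi] == "-"
    rna_seq[minus] <- revcomp(rna_seq[minus])

    bridge <- mutate_bridge(n, config$bridge_mutation_rate)
    read1 <- paste0(dna_seq, bridge$seq, rna_seq)
    rev_read <- runif(n) < 0.5
    read1[rev_read] <- revcomp(read1[rev_read])

    mate <- rna3_mates(ref, genes, gi)
    info <- data.frame(read_id = sprintf("read_%06d", seq_len(n)),
                       is_signal = !is_bg,
                       gene_id = gene_id,
                       bin = bin_id(b_chrom, b_start, b_start + config$bin_width),
                       dna_start = dna_start, dna_len = dna_len,
                       rna_start = rna_start, rna_len = rna_len,
                       reverse_oriented = rev_read,
                       bridge_substitutions = bridge$n_sub,
                       mate_valid3 = mate$valid,
                       stringsAsFactors = FALSE)
    list(read1 = read1, read2 = mate$seq, id = info$read_id, info = info)
  })
}

parse_bin_id <- function(x) {
  m <- regmatches(x, regexec("^(.+):(\\d+)-(\\d+)$", x))
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

# n mutated copies of the bridge; every flagged position is substituted with a
# different base, so the per-copy substitution count is exact bookkeeping.
mutate_bridge <- function(n, rate) {
  chars <- strsplit(BRIDGE_SEQUENCE, "")[[1]]
  mat <- matrix(rep(chars, each = n), nrow = n)
  if (rate > 0) {
    mask <- matrix(runif(n * length(chars)) < rate, nrow = n)
    idx <- which(mask)
    if (length(idx)) {
      alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
      mat[idx] <- alt[cbind(match(mat[idx], rownames(alt)),
                            sample.int(3L, length(idx), replace = TRUE))]
    }
    n_sub <- rowSums(mask)
  } else n_sub <- integer(n)
  list(seq = apply(mat, 1, paste, collapse = ""), n_sub = as.integer(n_sub))
}

# RNA 3'-end mates: 50-nt fragments whose transcript sequence begins with GGG.
rna3_mates <- function(ref, genes, gi) {
  tx <- extract_genome(ref$genome, genes$chrom, genes$start, genes$length)
  minus <- genes$strand == "-"
  tx[minus] <- revcomp(tx[minus])
  frag <- 50L
  cand <- lapply(seq_len(nrow(genes)), function(i) {
    p <- gregexpr("GGG", tx[i])[[1]]
    p <- p[p > 0 & p <= genes$length[i] - frag + 1L]
    p
  })
  valid <- lengths(cand[gi]) > 0
  q <- integer(length(gi))
  for (i in unique(gi)) {
    j <- which(gi == i)
    if (length(cand[[i]]) > 0) q[j] <- cand[[i]][sample.int(length(cand[[i]]), length(j), replace = TRUE)]
    else q[j] <- 1L
  }
  list(seq = substr(tx[gi], q, q + frag - 1L), valid = valid)
}

#' Generate per-nucleotide iCLIP crosslink tracks across replicates
#'
#' Planted binding sites deposit crosslink events at the three central
#' positions of each 7-nt site in every replicate, with high pooled scores, so
#' they satisfy the downstream calling rules (>= 3 covered positions, >= 4/5
#' replicate support). Expression-proportional background events and sparse,
#' low-score, replicate-inconsistent noise events are added on top. Also
#' returns the RNA-seq expression counts used for CPM filters and enrichment.
#'
#' @inheritParams generate_chimeric_fastq
#' @return List with `replicates` (list of `chrom, pos, count` data.frames,
#'   0-based positions), `scores` (pooled `chrom, pos, score`), `expression`
#'   (`gene_id, count`), and `library_size` (total crosslink events).
#' @export
generate_iclip_replicates <- function(config, ref, truth) {
  with_seed(config$seed + .rng_offsets[["iclip"]], {
    genes <- ref$genes
    ng <- nrow(genes)
    expr <- round(rlnorm(ng, log(200), 1))
    expr[sample.int(ng, round(0.15 * ng))] <- 0
    expr[match(truth$guides, genes$gene_id)] <-
      round(rlnorm(length(truth$guides), log(3000), 0.2))
    expr[match(truth$decoy_binders, genes$gene_id)] <-
      round(rlnorm(length(truth$decoy_binders), log(400), 0.2))

    nrep <- config$n_iclip_replicates
    ev <- list()  # chrom, pos, count, rep, score

    # Background events, expression-proportional; guides get extra pull-down.
    fac <- ifelse(genes$biotype == "lncRNA", 2, 1)
    fac[match(truth$guides, genes$gene_id)] <- 8
    nbg <- rpois(ng, expr * fac * 0.002)
    bi <- rep.int(seq_len(ng), nbg)
    if (length(bi)) {
      ev$bg <- data.frame(
        chrom = genes$chrom[bi],
        pos = genes$start[bi] + floor(runif(length(bi)) * genes$length[bi]),
        count = 1L,
        rep = sample.int(nrep, length(bi), replace = TRUE),
        score = runif(length(bi), 1, 4))
    }

    # Planted site events: three central positions, every replicate covered.
    ps <- truth$planted_binding_sites
    site_mean <- ifelse(ps$gene_id %in% truth$guides, 7, 2)
    ctr <- ps$start + 3L
    si <- rep(seq_len(nrow(ps)), each = 3L * nrep)
    off <- rep(rep(-1:1, times = nrep), times = nrow(ps))
    rp <- rep(rep(seq_len(nrep), each = 3L), times = nrow(ps))
    ev$site <- data.frame(
      chrom = ps$chrom[si],
      pos = ctr[si] + off,
      count = rpois(length(si), site_mean[si]) + 1L,
      rep = rp,
      score = ifelse(off == 0L, 10, 5) + runif(length(si), 0, 2))

    # Replicate-inconsistent low-score noise.
    nn <- config$iclip_noise_events * nrep
    if (nn > 0) {
      ni <- sample.int(ng, nn, replace = TRUE)
      ev$noise <- data.frame(
        chrom = genes$chrom[ni],
        pos = genes$start[ni] + floor(runif(nn) * genes$length[ni]),
        count = 1L,
        rep = rep(seq_len(nrep), each = config$iclip_noise_events),
        score = runif(nn, 0, 1))
    }

    allev <- do.call(rbind, ev)
    replicates <- lapply(seq_len(nrep), function(r) {
      d <- allev[allev$rep == r, c("chrom", "pos", "count")]
      agg <- aggregate(count ~ chrom + pos, data = d, FUN = sum)
      agg[order(agg$chrom, agg$pos), ]
    })
    sc <- aggregate(score ~ chrom + pos, data = allev, FUN = max)
    sc <- sc[order(sc$chrom, sc$pos), ]
    rownames(sc) <- NULL
    list(replicates = replicates,
         scores = sc,
         expression = data.frame(gene_id = genes$gene_id, count = expr,
                                 stringsAsFactors = FALSE),
         library_size = sum(allev$count))
  })
}

#' Generate peak count matrices for knockdown and PROTAC experiments
#'
#' Produces a replicate-tagged count matrix over the consensus peak set for
#' the control and each guide-knockdown condition (negative-binomial counts
#' around condition means; a knockdown divides the mean of its planted lost
#' peaks by `lost_fold`), plus single-pileup ATAC-style counts for a
#' control/PROTAC pair with per-condition sequencing depths.
#'
#' @inheritParams generate_chimeric_fastq
#' @return List with `peaks`, `counts` (long data.frame `peak_id, condition,
#'   replicate, count`), `atac` (`peak_id, control, protac`), `atac_depths`.
#' @export
generate_peaksets <- function(config, ref, truth) {
  with_seed(config$seed + .rng_offsets[["peaks"]], {
    peaks <- truth$peaks
    np <- nrow(peaks)
    base <- rlnorm(np, log(config$peak_mean_count), 0.4)
    conds <- c("control", paste0("si_", truth$guides))
    draw <- function(mu) {
      if (config$nb_dispersion == 0) round(mu)
      else rnbinom(np, mu = mu, size = 1 / config$nb_dispersion)
    }
    rows <- list()
    for (cd in conds) {
      mu <- base
      if (cd != "control") {
        g <- sub("^si_", "", cd)
        mu[peaks$peak_id %in% truth$knockdown_lost_peaks[[g]]] <-
          mu[peaks$peak_id %in% truth$knockdown_lost_peaks[[g]]] / config$lost_fold
      }
      for (r in seq_len(config$n_peak_replicates)) {
        rows[[paste(cd, r)]] <- data.frame(peak_id = peaks$peak_id,
                                           condition = cd, replicate = r,
                                           count = draw(mu),
                                           stringsAsFactors = FALSE)
      }
    }
    atac_base <- rlnorm(np, log(150), 0.3)
    mu_pro <- atac_base
    lost <- peaks$peak_id %in% truth$protac_lost_peaks
    mu_pro[lost] <- mu_pro[lost] / config$lost_fold
    atac <- data.frame(peak_id = peaks$peak_id,
                       control = rpois(np, atac_base),
                       protac = rpois(np, mu_pro),
                       stringsAsFactors = FALSE)
    # Both ATAC libraries are sequenced to the same total depth; reads from
    # collapsed peaks redistribute into background rather than shrinking the
    # library.
    depth <- round((sum(atac$control) + sum(atac$protac)) / 2) * 10
    list(peaks = peaks,
         counts = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         atac = atac,
         atac_depths = c(control = depth, protac = depth))
  })
}

#' Generate Hi-C loop/activity tables and DEG statistics tables
#'
#' Emits per-element accessibility activities, an element-to-gene Hi-C contact
#' table in which every planted loop clears the ABC threshold after per-gene
#' normalization (weak decoy contacts are added that cannot), and one DEG
#' statistics table per condition in which exactly the planted DEGs pass the
#' stated fold-change / adjusted-p / mean filters.
#'
#' @inheritParams generate_chimeric_fastq
#' @return List with `activities` (`element_id, activity`), `contacts`
#'   (`element_id, gene_id, contact`), and `deg_tables` (named list of
#'   `gene_id, log2fc, pvalue, padj, base_mean` data.frames).
#' @export
generate_hic_and_deg_inputs <- function(config, ref, truth) {
  with_seed(config$seed + .rng_offsets[["hic"]], {
    genes <- ref$genes
    peaks <- truth$peaks
    enh <- peaks[peaks$kind %in% c("target_enhancer", "protac_enhancer"), ]
    activities <- data.frame(element_id = enh$peak_id,
                             activity = runif(nrow(enh), 80, 120),
                             stringsAsFactors = FALSE)

    loops <- truth$loop_table
    contacts <- data.frame(element_id = loops$enhancer_id,
                           gene_id = loops$gene_id,
                           contact = runif(nrow(loops), 50, 100),
                           stringsAsFactors = FALSE)

    # Weak decoy contacts: same-chromosome enhancers near the gene TSS whose
    # activity x contact share stays below the ABC threshold by construction.
    looped_genes <- unique(loops$gene_id)
    dec <- list()
    for (g in looped_genes) {
      row <- genes[genes$gene_id == g, ]
      nd <- sample(0:3, 1)
      if (nd == 0) next
      near <- enh$peak_id[enh$chrom == row$chrom &
                            abs((enh$start + enh$end) / 2 - row$tss) <= 5e6]
      near <- setdiff(near, loops$enhancer_id[loops$gene_id == g])
      if (!length(near)) next
      pick <- sample(near, min(nd, length(near)))
      dec[[g]] <- data.frame(element_id = pick, gene_id = g,
                             contact = runif(length(pick), 0.1, 0.5),
                             stringsAsFactors = FALSE)
    }
    if (length(dec)) contacts <- rbind(contacts, do.call(rbind, dec))
    rownames(contacts) <- NULL

    deg_tables <- lapply(names(truth$planted_degs), function(cond) {
      degs <- truth$planted_degs[[cond]]
      is_deg <- genes$gene_id %in% degs
      nge <- nrow(genes)
      lfc <- rnorm(nge, 0, 0.15)
      lfc <- pmin(pmax(lfc, -0.55), 0.55)
      lfc[is_deg] <- -runif(sum(is_deg), 1.0, 2.5)
      padj <- runif(nge, 0.2, 1)
      padj[is_deg] <- 10^-runif(sum(is_deg), 2, 8)
      bm <- rlnorm(nge, log(100), 0.5)
      bm[is_deg] <- 20 + rlnorm(sum(is_deg), log(150), 0.5)
      data.frame(gene_id = genes$gene_id, log2fc = lfc, pvalue = padj / 2,
                 padj = padj, base_mean = bm, stringsAsFactors = FALSE)
    })
    names(deg_tables) <- names(truth$planted_degs)
    list(activities = activities, contacts = contacts, deg_tables = deg_tables)
  })
}

#' Generate chromatin-state segmentations for several cell types
#'
#' The target cell type carries `Strong_Enhancer` at every planted enhancer
#' peak; the other cell types carry `Repressed` or `Quiescent` there, so the
#' planted enhancers are target-cell specific. Promoter windows around every
#' TSS are `Active_Promoter` in all cell types; everything else is
#' `Quiescent`. Each segmentation tiles the genome without overlap.
#'
#' @inheritParams generate_chimeric_fastq
#' @param cells Cell-type labels; the first is the target cell.
#' @return Named list of `chrom, start, end, state` data.frames (0-based
#'   half-open).
#' @export
generate_segmentations <- function(config, ref, truth,
                                   cells = c("huvec", "cellB", "cellC")) {
  genes <- ref$genes
  peaks <- truth$peaks
  enh <- peaks[peaks$kind %in% c("target_enhancer", "protac_enhancer"), ]
  gr_enh <- GenomicRanges::reduce(GenomicRanges::GRanges(
    enh$chrom, IRanges::IRanges(enh$start + 1, enh$end)))
  gr_prom <- GenomicRanges::reduce(GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(genes$tss - 500, 0) + 1, genes$tss + 500)))
  gr_prom <- GenomicRanges::setdiff(gr_prom, gr_enh)
  whole <- GenomicRanges::GRanges(names(ref$chrom_sizes),
                                  IRanges::IRanges(1, ref$chrom_sizes))
  rest <- GenomicRanges::setdiff(whole, GenomicRanges::union(gr_enh, gr_prom))
  to_df <- function(gr, state) data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    state = state, stringsAsFactors = FALSE)
  enh_states <- setNames(c("Strong_Enhancer",
                           rep(c("Repressed", "Quiescent"),
                               length.out = length(cells) - 1)), cells)
  segs <- lapply(cells, function(cl) {
    d <- rbind(to_df(gr_enh, enh_states[[cl]]),
               to_df(gr_prom, "Active_Promoter"),
               to_df(rest, "Quiescent"))
    d <- d[order(d$chrom, d$start), ]
    rownames(d) <- NULL
    d
  })
  names(segs) <- cells
  segs
}

#' Simulate the full multi-omic dataset
#'
#' Runs every generator in sequence and bundles the results with the planted
#' ground-truth manifest.
#'
#' @param config A [synthetic_config()].
#' @return A `triad_simulation` list with `config, ref, truth, fastq, iclip,
#'   peaksets, hic, segmentations`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  ref <- generate_reference(config)
  truth <- plant_truth(config, ref)
  fastq <- generate_chimeric_fastq(config, ref, truth)
  iclip <- generate_iclip_replicates(config, ref, truth)
  peaksets <- generate_peaksets(config, ref, truth)
  hic <- generate_hic_and_deg_inputs(config, ref, truth)
  segmentations <- generate_segmentations(config, ref, truth)
  structure(list(config = config, ref = ref, truth = truth, fastq = fastq,
                 iclip = iclip, peaksets = peaksets, hic = hic,
                 segmentations = segmentations),
            class = "triad_simulation")
}

#' Write a simulated dataset to standard plain-text formats
#'
#' FASTA genome, tab-separated gene annotation, paired FASTQ, one bedGraph per
#' iCLIP replicate plus a pooled score bedGraph, BED/TSV peak and count
#' tables, loop and DEG TSVs, one segmentation BED per cell type, and the
#' ground-truth manifest as JSON.
#'
#' @param sim Output of [simulate_dataset()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  Biostrings::writeXStringSet(sim$ref$genome, p("genome.fa"))
  tsv <- function(d, f) write.table(d, p(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  tsv(sim$ref$genes, "genes.tsv")
  write_fastq(sim$fastq$read1, sim$fastq$id, p("reads_1.fastq"))
  write_fastq(sim$fastq$read2, sim$fastq$id, p("reads_2.fastq"))
  for (r in seq_along(sim$iclip$replicates)) {
    d <- sim$iclip$replicates[[r]]
    write.table(data.frame(d$chrom, d$pos, d$pos + 1L, d$count),
                p(sprintf("iclip_rep%d.bedgraph", r)), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  s <- sim$iclip$scores
  write.table(data.frame(s$chrom, s$pos, s$pos + 1L, s$score),
              p("iclip_scores.bedgraph"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tsv(sim$iclip$expression, "expression.tsv")
  tsv(sim$peaksets$peaks, "peaks.tsv")
  tsv(sim$peaksets$counts, "peak_counts.tsv")
  tsv(sim$peaksets$atac, "atac_pileups.tsv")
  tsv(sim$hic$activities, "activities.tsv")
  tsv(sim$hic$contacts, "hic_contacts.tsv")
  for (cond in names(sim$hic$deg_tables))
    tsv(sim$hic$deg_tables[[cond]], sprintf("deg_%s.tsv", cond))
  for (cl in names(sim$segmentations)) {
    d <- sim$segmentations[[cl]]
    write.table(d, p(sprintf("segmentation_%s.bed", cl)), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  truth <- sim$truth
  truth$peaks <- NULL  # tabular; stored separately
  tsv(sim$truth$peaks, "truth_peaks.tsv")
  jsonlite::write_json(unclass(truth), p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}

write_fastq <- function(seqs, ids, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
}
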