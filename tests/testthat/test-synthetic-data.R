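test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(biotype_fractions = c(lncRNA = 0.5, protein_coding = 0.5,
                                                      snoRNA = 0, snRNA = 0, miRNA = 0.1)),
               "sum to 1")
  expect_error(synthetic_config(chromosome_length = 5e4), "20 bin widths")
  expect_error(synthetic_config(bridge_mutation_rate = 1.2), "bridge_mutation_rate")
  expect_error(synthetic_config(loops_per_enhancer = c(5, 1)), "loops_per_enhancer")
})

test_that("reference has the configured genes, biotype counts and no bridge copy", {
  cfg <- small_config()
  ref <- small_sim()$ref
  genes <- ref$genes
  expect_equal(nrow(genes), cfg$n_genes)
  expect_equal(length(ref$genome), cfg$n_chromosomes)
  tb <- table(genes$biotype)
  for (b in names(cfg$biotype_fractions))
    expect_lte(abs(tb[[b]] - cfg$biotype_fractions[[b]] * cfg$n_genes), 1)
  # non-overlapping genes per chromosome
  for (cn in unique(genes$chrom)) {
    g <- genes[genes$chrom == cn, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  for (cn in names(ref$genome)) {
    expect_equal(Biostrings::countPattern(BRIDGE_SEQUENCE, ref$genome[[cn]]), 0)
    expect_equal(Biostrings::countPattern(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(BRIDGE_SEQUENCE))),
      ref$genome[[cn]]), 0)
  }
})

test_that("generation is byte-deterministic under the seed", {
  cfg <- synthetic_config(seed = 5, n_contacts = 300L, n_genes = 60L,
                          n_decoy_binders = 5L, n_background_peaks = 40L,
                          n_protac_only_enhancers = 30L, targets_per_guide = 8L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.character(a$ref$genome), as.character(b$ref$genome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$fastq, b$fastq)
  expect_identical(a$iclip, b$iclip)
  expect_identical(a$peaksets, b$peaksets)
  expect_identical(a$hic, b$hic)
})

test_that("an unplaceable gene load raises a sizing error", {
  cfg <- synthetic_config(n_genes = 200L, chromosome_length = 6e5,
                          n_chromosomes = 1L)
  expect_error(generate_reference(cfg), "too small")
})

test_that("planted targets obey the distal (trans) rule", {
  sim <- small_sim()
  genes <- sim$ref$genes
  for (g in names(sim$truth$guide_targets)) {
    row <- genes[genes$gene_id == g, ]
    for (b in sim$truth$guide_targets[[g]]) {
      m <- regmatches(b, regexec("^(.+):(\\d+)-(\\d+)$", b))[[1]]
      if (m[2] != row$chrom) next
      gap <- max(as.integer(m[3]) - row$end, row$start - as.integer(m[4]))
      expect_gt(gap, 5e6)
    }
  }
})

test_that("ground truth is internally consistent", {
  truth <- small_sim()$truth
  # every knockdown-lost peak is one of its guide's target-bin enhancer peaks
  pk <- truth$peaks
  for (g in names(truth$knockdown_lost_peaks)) {
    ids <- truth$knockdown_lost_peaks[[g]]
    coords <- pk[match(ids, pk$peak_id), ]
    expect_true(all(bin_id(coords$chrom, coords$start, coords$end)
                    %in% truth$guide_targets[[g]]))
  }
  # every planted DEG is reachable from a lost enhancer through the loop table
  for (cond in names(truth$planted_degs)) {
    lost <- if (cond == "protac") truth$protac_lost_peaks
            else truth$knockdown_lost_peaks[[sub("^si_", "", cond)]]
    reachable <- truth$loop_table$gene_id[truth$loop_table$enhancer_id %in% lost]
    expect_true(all(truth$planted_degs[[cond]] %in% reachable))
  }
})

test_that("chimeric reads match the planted construction", {
  cfg <- small_config()
  sim <- small_sim()
  info <- sim$fastq$info
  # background fraction within 3 binomial SDs
  n <- nrow(info)
  p <- cfg$background_contact_fraction
  expect_lte(abs(sum(!info$is_signal) - p * n), 3 * sqrt(n * p * (1 - p)))
  # read geometry: 100-nt chimeric mates, both parts >= 20 nt
  expect_true(all(nchar(sim$fastq$read1) == 100L))
  expect_true(all(info$dna_len >= 20L & info$rna_len >= 20L))
})

test_that("zero bridge mutation rate gives exact bridge copies in every read", {
  cfg <- synthetic_config(seed = 9, n_contacts = 400L, bridge_mutation_rate = 0)
  ref <- generate_reference(cfg)
  truth <- plant_truth(cfg, ref)
  fq <- generate_chimeric_fastq(cfg, ref, truth)
  fwd <- Biostrings::vcountPattern(BRIDGE_SEQUENCE,
                                   Biostrings::DNAStringSet(fq$read1))
  rev <- Biostrings::vcountPattern(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(BRIDGE_SEQUENCE))),
    Biostrings::DNAStringSet(fq$read1))
  expect_true(all(fwd + rev >= 1L))
  expect_true(all(fq$info$bridge_substitutions == 0L))
})

test_that("planted iCLIP sites satisfy the calling rules by construction", {
  sim <- small_sim()
  cfg <- small_config()
  ps <- sim$truth$planted_binding_sites
  pooled <- do.call(rbind, sim$iclip$replicates)
  for (i in sample(nrow(ps), 20)) {
    win <- (ps$start[i]):(ps$end[i] - 1L)
    covered <- length(unique(pooled$pos[pooled$chrom == ps$chrom[i] &
                                          pooled$pos %in% win]))
    expect_gte(covered, 3L)
    support <- sum(vapply(sim$iclip$replicates, function(r)
      any(r$chrom == ps$chrom[i] & r$pos %in% win), TRUE))
    expect_gte(support, 4L)
  }
})

test_that("peak counts drop at planted lost peaks and dispersion zero is exact", {
  cfg <- synthetic_config(seed = 4, n_contacts = 100L, nb_dispersion = 0,
                          n_protac_only_enhancers = 50L,
                          n_background_peaks = 40L)
  ref <- generate_reference(cfg)
  truth <- plant_truth(cfg, ref)
  ps <- generate_peaksets(cfg, ref, truth)
  ctrl <- ps$counts[ps$counts$condition == "control" & ps$counts$replicate == 1, ]
  g1 <- truth$guides[1]
  kd <- ps$counts[ps$counts$condition == paste0("si_", g1) & ps$counts$replicate == 1, ]
  lost <- ctrl$peak_id %in% truth$knockdown_lost_peaks[[g1]]
  # dispersion 0: counts equal rounded means, so the planted fold is exact
  ratio <- ctrl$count[lost] / pmax(kd$count[lost], 1)
  expect_true(all(ratio > cfg$lost_fold / 2))
  expect_identical(ctrl$count[!lost], kd$count[!lost])
  # replicates identical at dispersion 0
  r2 <- ps$counts[ps$counts$condition == "control" & ps$counts$replicate == 2, ]
  expect_identical(ctrl$count, r2$count)
})

test_that("every planted loop clears the ABC threshold and decoys do not", {
  sim <- small_sim()
  elements <- data.frame(
    element_id = sim$hic$activities$element_id,
    sim$truth$peaks[match(sim$hic$activities$element_id, sim$truth$peaks$peak_id),
                    c("chrom", "start", "end")],
    activity = sim$hic$activities$activity, stringsAsFactors = FALSE)
  links <- compute_abc(elements, sim$hic$contacts, sim$ref$genes,
                       integration_config())
  planted <- paste(sim$truth$loop_table$enhancer_id, sim$truth$loop_table$gene_id)
  kept <- paste(links$element_id, links$gene_id)
  expect_true(all(planted %in% kept))
  # decoy links (contact < 1) must all fall below the threshold
  decoy <- sim$hic$contacts$contact < 1
  expect_false(any(paste(sim$hic$contacts$element_id[decoy],
                         sim$hic$contacts$gene_id[decoy]) %in% kept))
})

test_that("DEG tables pass exactly the planted genes through the stated filters", {
  sim <- small_sim()
  for (cond in names(sim$hic$deg_tables)) {
    fl <- filter_degs(sim$hic$deg_tables[[cond]], integration_config())
    expect_setequal(fl$gene_id[fl$is_deg], sim$truth$planted_degs[[cond]])
  }
})

test_that("write_simulation emits the expected plain-text files", {
  cfg <- synthetic_config(seed = 3, n_contacts = 200L, n_genes = 60L,
                          n_decoy_binders = 5L, n_background_peaks = 40L,
                          n_protac_only_enhancers = 30L, targets_per_guide = 8L)
  sim <- simulate_dataset(cfg)
  out <- withr::local_tempdir()
  write_simulation(sim, out)
  expect_true(all(file.exists(file.path(out, c(
    "genome.fa", "genes.tsv", "reads_1.fastq", "reads_2.fastq",
    "iclip_rep1.bedgraph", "iclip_scores.bedgraph", "expression.tsv",
    "peaks.tsv", "peak_counts.tsv", "atac_pileups.tsv", "activities.tsv",
    "hic_contacts.tsv", "segmentation_huvec.bed", "truth.json")))))
  fq <- Biostrings::readDNAStringSet(file.path(out, "reads_1.fastq"), format = "fastq")
  expect_equal(length(fq), cfg$n_contacts)
})
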