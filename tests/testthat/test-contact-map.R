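test_that("make_bins tiles chromosomes half-open with a short terminal bin", {
  b <- make_bins(c(chr1 = 12000), contact_config(bin_width = 5000))
  expect_equal(b$start, c(0, 5000, 10000))
  expect_equal(b$end, c(5000, 10000, 12000))
  one <- make_bins(c(chr1 = 3000), contact_config(bin_width = 5000))
  expect_equal(nrow(one), 1L)
  expect_equal(one$end, 3000)
  sizes <- c(chr1 = 12345, chr2 = 100, chr3 = 50000)
  b <- make_bins(sizes, contact_config(bin_width = 5000))
  expect_equal(nrow(b), sum(ceiling(sizes / 5000)))
  expect_warning(make_bins(c(chr1 = 1000, chrM = 0),
                           contact_config(bin_width = 500)), "zero-length")
})

make_parts_row <- function(read_id, dna = c("chr1", 100L), rna5 = c("chr1", 1500L),
                           rna3 = c("chr1", 1600L), dna_unique = TRUE,
                           rna5_unique = TRUE, rna3_unique = TRUE, valid3 = TRUE) {
  data.frame(read_id = read_id, valid3 = valid3,
             dna_chrom = dna[1], dna_pos = as.integer(dna[2]), dna_strand = "+",
             dna_len = 30L, dna_unique = dna_unique,
             rna5_chrom = rna5[1], rna5_pos = as.integer(rna5[2]), rna5_strand = "+",
             rna5_len = 30L, rna5_unique = rna5_unique,
             rna3_chrom = rna3[1], rna3_pos = as.integer(rna3[2]), rna3_strand = "+",
             rna3_len = 50L, rna3_unique = rna3_unique,
             stringsAsFactors = FALSE)
}

test_that("assign_contacts applies the same-gene and uniqueness rules", {
  genes <- toy_genes()
  bins <- make_bins(c(chr1 = 30000, chr2 = 10000), contact_config(bin_width = 5000))
  parts <- rbind(
    make_parts_row("r1"),                                        # valid: gA
    make_parts_row("r2", rna3 = c("chr1", 21000L)),              # mates in gA and gB
    make_parts_row("r3", dna_unique = FALSE),                    # multi-mapped DNA
    make_parts_row("r4", rna5 = c("chr1", 10000L),
                   rna3 = c("chr1", 10100L)),                    # RNA outside genes
    make_parts_row("r5", valid3 = FALSE))                        # invalid 3' mate
  tab <- assign_contacts(parts, genes, bins)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$rna_gene_id, "gA")
  expect_equal(tab$start, 0L)
  expect_equal(tab$raw_count, 1L)
  dr <- attr(tab, "drops")
  expect_equal(unname(dr[["rna_mates_different_genes"]]), 1L)
  expect_equal(unname(dr[["dna_not_unique"]]), 1L)
  expect_equal(unname(dr[["rna_outside_gene"]]), 1L)
  expect_equal(unname(dr[["invalid_rna3"]]), 1L)
})

test_that("normalization conserves the scale and is depth-invariant", {
  cfg <- contact_config()
  tab <- data.frame(rna_gene_id = c("g1", "g2"), chrom = "chr1",
                    start = c(0L, 5000L), end = c(5000L, 10000L),
                    raw_count = c(3L, 7L))
  nm <- normalize_contacts(tab, cfg)
  expect_equal(sum(nm$normalized_frequency), cfg$norm_scale)
  single <- normalize_contacts(data.frame(rna_gene_id = "g", chrom = "chr1",
                                          start = 0L, end = 5000L, raw_count = 1L), cfg)
  expect_equal(single$normalized_frequency, 1e6)
  doubled <- tab; doubled$raw_count <- doubled$raw_count * 2L
  expect_equal(normalize_contacts(doubled, cfg)$normalized_frequency,
               nm$normalized_frequency)
  empty <- normalize_contacts(tab[0, ], cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("cis/trans classification follows the strict >5 Mb gap rule", {
  cfg <- contact_config()
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 1000000L,
                      end = 1010000L, stringsAsFactors = FALSE)
  mk <- function(chrom, s, e) data.frame(rna_gene_id = "g", chrom = chrom,
                                         start = s, end = e, raw_count = 1L)
  expect_equal(classify_cis_trans(mk("chr1", 7000000L, 7005000L), genes, cfg)$rna_class,
               "trans")  # gap 5,990,000
  expect_equal(classify_cis_trans(mk("chr1", 1002000L, 1007000L), genes, cfg)$rna_class,
               "cis")    # overlaps the gene
  expect_equal(classify_cis_trans(mk("chr1", 6010000L, 6015000L), genes, cfg)$rna_class,
               "cis")    # gap exactly 5,000,000: strictly more-than rule
  expect_equal(classify_cis_trans(mk("chr1", 6010001L, 6015001L), genes, cfg)$rna_class,
               "trans")
  expect_equal(classify_cis_trans(mk("chr2", 0L, 5000L), genes, cfg)$rna_class,
               "trans")
})

test_that("classification agrees with a brute-force distance oracle on synthetic contacts", {
  sim <- small_sim()
  tab <- small_pipeline()$contacts
  genes <- sim$ref$genes
  for (i in sample(nrow(tab), 500)) {
    g <- genes[genes$gene_id == tab$rna_gene_id[i], ]
    want <- if (g$chrom != tab$chrom[i]) "trans" else {
      gap <- max(0, g$start - tab$end[i], tab$start[i] - g$end)
      if (gap > 5e6) "trans" else "cis"
    }
    expect_identical(tab$rna_class[i], want)
  }
})

test_that("frequency strata compare two libraries with undefined empty strata", {
  cfg <- contact_config()
  tab <- normalize_contacts(data.frame(
    rna_gene_id = paste0("g", 1:10), chrom = "chr1",
    start = seq(0L, by = 5000L, length.out = 10),
    end = seq(5000L, by = 5000L, length.out = 10),
    raw_count = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 5L, 10L, 24L)), cfg)
  fd <- frequency_distribution(tab, tab, breaks = c(0, 5e4, 1e5, 5e5, Inf))
  expect_true(all(fd$fold_change[fd$n_a > 0] == 1))
  expect_true(all(is.na(fd$fold_change[fd$n_a == 0])))
  expect_equal(sum(fd$n_a), nrow(tab))

  # duplicating high-frequency pairs inflates only high strata
  hi <- tab[tab$normalized_frequency > 1e5, ]
  tab_b <- rbind(tab, hi)
  fd2 <- frequency_distribution(tab, tab_b, breaks = c(0, 5e4, 1e5, 5e5, Inf))
  low <- fd2$n_a > 0 & seq_len(nrow(fd2)) < 3
  expect_true(all(fd2$fold_change[low] == 1))
  expect_true(any(fd2$fold_change[-which(low)] > 1, na.rm = TRUE))

  bad <- tab
  attr(bad, "norm_scale") <- 1e3
  expect_error(frequency_distribution(tab, bad), "different scales")
})

test_that("peak containment labels and the signed-rank pairing behave", {
  cfg <- contact_config()
  tab <- normalize_contacts(data.frame(
    rna_gene_id = rep(c("g1", "g2", "g3"), each = 4), chrom = "chr1",
    start = seq(0L, by = 5000L, length.out = 12),
    end = seq(5000L, by = 5000L, length.out = 12),
    raw_count = c(9L, 8L, 1L, 1L, 7L, 9L, 2L, 1L, 8L, 9L, 1L, 2L)), cfg)
  allpeaks <- data.frame(chrom = "chr1", start = 0L, end = 60000L)
  expect_warning(res_all <- peak_overlap_frequencies(tab, allpeaks), "skipped")
  expect_true(all(res_all$in_peak))

  # a peak equal to one bin marks exactly that bin
  one <- peak_overlap_frequencies(tab, data.frame(chrom = "chr1", start = 5000L,
                                                  end = 10000L))
  expect_equal(which(one$in_peak), 2L)

  expect_warning(
    peak_overlap_frequencies(tab, data.frame(chrom = "chr9", start = 0L, end = 10L)),
    "skipped")
})

test_that("signed-rank p matches exact enumeration over all sign assignments", {
  set.seed(71)
  for (n in c(6, 8, 10)) {
    repeat {  # draw until no zero differences or tied magnitudes
      x <- round(runif(n, 1, 20), 3)
      y <- round(runif(n, 1, 20), 3)
      d <- x - y
      if (all(d != 0) && !anyDuplicated(abs(d))) break
    }
    got <- wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(got, oracle_signed_rank_p(x, y), tolerance = 1e-12)
  }
})

test_that("contacts planted preferentially inside peaks give a significant test", {
  # per-gene construction: in-peak bins carry systematically more contacts
  set.seed(72)
  cfg <- contact_config()
  rows <- list()
  for (g in 1:30) {
    starts <- (seq_len(4) - 1L + (g - 1L) * 4L) * 5000L
    rows[[g]] <- data.frame(rna_gene_id = sprintf("g%02d", g), chrom = "chr1",
                            start = starts, end = starts + 5000L,
                            raw_count = c(sample(6:15, 2, TRUE),
                                          sample(1:5, 2, TRUE)))
  }
  tab <- normalize_contacts(do.call(rbind, rows), cfg)
  in_bins <- tab[rep(c(TRUE, TRUE, FALSE, FALSE), 30), ]
  peaks <- data.frame(chrom = "chr1", start = in_bins$start + 2000L,
                      end = in_bins$start + 3000L)
  pf <- peak_overlap_frequencies(tab, peaks)
  expect_equal(sum(pf$in_peak), 60L)
  expect_lt(pf$p_value, 0.01)
  expect_gt(mean(pf$pairs$mean_in), mean(pf$pairs$mean_out))
})

test_that("shuffled peaks preserve lengths and chromosomes without overlap", {
  peaks <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(100L, 5000L, 0L),
                      end = c(1100L, 5600L, 800L))
  sizes <- c(chr1 = 50000, chr2 = 10000)
  sh <- shuffle_peaks(peaks, sizes, seed = 3)
  expect_identical(sh$chrom, peaks$chrom)
  expect_equal(sh$end - sh$start, peaks$end - peaks$start)
  expect_true(all(sh$start >= 0 & sh$end <= sizes[sh$chrom]))
  for (cn in unique(sh$chrom)) {
    p <- sh[sh$chrom == cn, ]
    p <- p[order(p$start), ]
    if (nrow(p) > 1) expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  }
  expect_identical(shuffle_peaks(peaks, sizes, seed = 3), sh)
  expect_false(identical(shuffle_peaks(peaks, sizes, seed = 4), sh))
  # per-chromosome total peak bp conserved
  expect_equal(tapply(sh$end - sh$start, sh$chrom, sum),
               tapply(peaks$end - peaks$start, peaks$chrom, sum))
  crowded <- data.frame(chrom = "c", start = c(0L, 0L), end = c(900L, 900L))
  expect_error(shuffle_peaks(crowded, c(c = 1000), seed = 1, max_tries = 5),
               "crowded")
})

test_that("shuffling peaks destroys the planted in-peak enrichment", {
  sim <- small_sim()
  res <- small_pipeline()
  enh <- sim$truth$peaks[sim$truth$peaks$kind == "target_enhancer", ]
  ps <- vapply(1:20, function(s) {
    sh <- shuffle_peaks(enh, sim$ref$chrom_sizes, seed = s)
    suppressWarnings(peak_overlap_frequencies(res$contacts, sh)$p_value)
  }, 1)
  expect_gte(mean(ps > 0.05, na.rm = TRUE), 0.9)
})
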