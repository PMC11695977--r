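#' Configuration for the synthetic multi-omic dataset
#'
#' Bundles every tunable of the planted-truth simulator: a miniature genome,
#' gene annotation with biotypes, guide lncRNAs with distal (>5 Mb or
#' interchromosomal) target enhancer bins, bridge-adapter chimeric reads,
#' per-nucleotide iCLIP crosslink tracks over replicates, knockdown/PROTAC
#' peak count matrices, and loop/DEG tables. Defaults define the reference
#' study conditions used throughout the test-suite.
#'
#' @param seed Integer master seed. Each artifact type draws from its own
#'   stream seeded as `seed + offset`, so regenerating one file does not
#'   perturb the others.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bp.
#' @param n_genes Total genes to place (non-overlapping).
#' @param biotype_fractions Named proportions over
#'   `lncRNA, protein_coding, snoRNA, snRNA, miRNA`; must sum to 1.
#' @param n_guides Number of planted guide lncRNAs.
#' @param targets_per_guide Distal target enhancer bins per guide.
#' @param n_contacts Total chimeric read pairs.
#' @param background_contact_fraction Proportion of read pairs drawn uniformly
#'   (random gene x random bin) rather than from planted guide--target pairs.
#' @param bridge_mutation_rate Per-base substitution probability applied to the
#'   bridge copy embedded in each read.
#' @param n_iclip_replicates Number of iCLIP replicate tracks.
#' @param loops_per_enhancer Integer range (length-2 vector) of promoters each
#'   lost enhancer loops to.
#' @param bin_width DNA bin width in bp used for planting targets (5 kb, the
#'   contact-map resolution).
#' @param n_decoy_binders Non-guide lncRNAs given a few weak planted binding
#'   sites so candidate ranking has competition.
#' @param sites_per_guide Planted 7-nt binding sites per guide lncRNA.
#' @param n_background_peaks Stable (never lost) peaks added to the consensus
#'   peak set.
#' @param n_protac_only_enhancers Enhancer-state peaks lost after PROTAC but
#'   not after any knockdown; sets the planted attribution fraction.
#' @param peak_mean_count Mean replicate read count at an unperturbed peak.
#' @param lost_fold Fold reduction of the mean at a lost peak.
#' @param nb_dispersion Negative-binomial dispersion of replicate counts.
#' @param n_peak_replicates Replicates per condition in count matrices.
#' @param iclip_noise_events Replicate-inconsistent single-position noise
#'   crosslink events per replicate (genome-wide).
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 3L,
                             chromosome_length = 12e6,
                             n_genes = 300L,
                             biotype_fractions = c(lncRNA = 0.25,
                                                   protein_coding = 0.60,
                                                   snoRNA = 0.05,
                                                   snRNA = 0.05,
                                                   miRNA = 0.05),
                             n_guides = 5L,
                             targets_per_guide = 40L,
                             n_contacts = 100000L,
                             background_contact_fraction = 0.3,
                             bridge_mutation_rate = 0.02,
                             n_iclip_replicates = 5L,
                             loops_per_enhancer = c(1L, 5L),
                             bin_width = 5000L,
                             n_decoy_binders = 15L,
                             sites_per_guide = 10L,
                             n_background_peaks = 300L,
                             n_protac_only_enhancers = 800L,
                             peak_mean_count = 100,
                             lost_fold = 8,
                             nb_dispersion = 0.1,
                             n_peak_replicates = 3L,
                             iclip_noise_events = 1000L) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes = as.integer(n_genes),
              biotype_fractions = biotype_fractions,
              n_guides = as.integer(n_guides),
              targets_per_guide = as.integer(targets_per_guide),
              n_contacts = as.integer(n_contacts),
              background_contact_fraction = background_contact_fraction,
              bridge_mutation_rate = bridge_mutation_rate,
              n_iclip_replicates = as.integer(n_iclip_replicates),
              loops_per_enhancer = as.integer(loops_per_enhancer),
              bin_width = as.integer(bin_width),
              n_decoy_binders = as.integer(n_decoy_binders),
              sites_per_guide = as.integer(sites_per_guide),
              n_background_peaks = as.integer(n_background_peaks),
              n_protac_only_enhancers = as.integer(n_protac_only_enhancers),
              peak_mean_count = peak_mean_count,
              lost_fold = lost_fold,
              nb_dispersion = nb_dispersion,
              n_peak_replicates = as.integer(n_peak_replicates),
              iclip_noise_events = as.integer(iclip_noise_events))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  wanted <- c("lncRNA", "protein_coding", "snoRNA", "snRNA", "miRNA")
  if (!setequal(names(cfg$biotype_fractions), wanted))
    stop("biotype_fractions must be named over: ", paste(wanted, collapse = ", "))
  if (abs(sum(cfg$biotype_fractions) - 1) > 1e-9)
    stop("biotype_fractions must sum to 1")
  if (cfg$chromosome_length < 20L * cfg$bin_width)
    stop("chromosome_length must be at least 20 bin widths")
  if (cfg$background_contact_fraction < 0 || cfg$background_contact_fraction > 1)
    stop("background_contact_fraction must be in [0, 1]")
  if (cfg$bridge_mutation_rate < 0 || cfg$bridge_mutation_rate >= 1)
    stop("bridge_mutation_rate must be in [0, 1)")
  if (length(cfg$loops_per_enhancer) != 2L ||
      cfg$loops_per_enhancer[1] < 1L ||
      cfg$loops_per_enhancer[2] < cfg$loops_per_enhancer[1])
    stop("loops_per_enhancer must be an increasing integer range, minimum 1")
  if (cfg$n_guides < 1L || cfg$targets_per_guide < 1L)
    stop("n_guides and targets_per_guide must be positive")
  invisible(cfg)
}

# RNG stream offsets, one per artifact type (see synthetic_config docs).
.rng_offsets <- c(reference = 101L, truth = 202L, fastq = 303L, iclip = 404L,
                  peaks = 505L, hic = 606L, segmentation = 707L)
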