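# triadmap

Integrative analysis of how **trans-acting long non-coding RNAs target the
SWI/SNF chromatin remodeler (BRG1) to cell-type-specific enhancers**, from
three complementary assay families:

* RNA–DNA proximity ligation (Red-C / RedChIP-style chimeric reads with a
  bridge adapter) → genome-wide RNA-gene × 5-kb-bin contact maps,
* iCLIP crosslink tracks → reproducible 7-nt protein–RNA binding sites and a
  ranked shortlist of candidate guide lncRNAs,
* perturbation chromatin data (CUT&RUN under lncRNA knockdowns, ATAC under
  acute PROTAC degradation, Hi-C loops, RNA-seq) → lost enhancers, their
  target genes, and enhancer-hub statistics.

The package is written for regulatory-genomics analysts who want the full
decision chain of this experimental design as tested, reusable functions —
plus a synthetic multi-omic generator with a planted ground truth, so the
entire pipeline runs and is validated end to end with no downloads.

## The core statistics

* **Bridge-adapter chimera splitting.** Reads are scanned for the 37-nt
  bridge (either orientation, ≤4 mismatches, full-length occurrences only);
  minimum-mismatch hits split each read into a DNA part and an RNA 5' part
  (both ≥14 nt), with valid RNA 3' mates required (`^GGG`/`CCC$`). Uniquely
  mapped parts yield contacts: a pair counts for (gene, bin) iff both RNA
  alignments fall in the same gene. Frequencies are contacts per million
  valid contacts; a contact is *trans* iff interchromosomal or >5 Mb from
  the gene locus.
* **Binding-site calling.** After dropping the lowest-scoring 2% of
  crosslink positions, 7-nt sites are greedily seeded in descending score
  order, then filtered to ≥3 event-covered positions and support in ≥4 of 5
  replicates. Candidate lncRNAs are ranked by the mean of four z-scaled
  metrics (iCLIP coverage, expression, enrichment, number of sites).
* **Differential binding.** FRiP-normalized replicate counts are tested on
  the log2 scale with an empirical-Bayes moderated t statistic
  (BH-adjusted, FDR < 0.05); two-condition ATAC pileups use the Poisson
  log-likelihood ratio `(x1 ln(x1/m) + x2 ln(x2/m))/ln 10`, `m = (x1+x2)/2`,
  with the 3.84 decision threshold.
* **Enhancer–gene links.** Adapted activity-by-contact score
  `ABC(e,g) = A_e C_eg / Σ_{e'∈±5 Mb} A_{e'} C_{e'g}` at 1-kb Hi-C
  resolution, links kept at ABC > 0.02; DEGs at |log2FC| ≥ 0.59,
  BH p ≤ 0.05, mean ≥ 5. Lost-enhancer sets are combined into upset
  intersections, PROTAC-attribution fractions, and DEG hub degrees.

See `vignettes/triadmap-methods.Rmd` for the full model description,
parameter table, and design rationale.

## Worked example

Simulate the default study conditions at reduced read depth, run every
stage, and score recovery against the planted manifest:

```r
library(triadmap)
sim <- simulate_dataset(synthetic_config(seed = 7, n_contacts = 20000L))
res <- run_pipeline(sim)

head(res$candidates$ranked[, c("gene_id", "composite", "rank")], 8)
#>     gene_id composite rank
#> 1 gene_0162 3.5271110    1
#> 2 gene_0122 3.0070079    2
#> 3 gene_0171 2.7096001    3
#> 4 gene_0061 2.3991267    4
#> 5 gene_0007 2.3515376    5
#> 6 gene_0158 0.6600995    6
#> 7 gene_0185 0.5409241    7
#> 8 gene_0102 0.4771126    8
```

The five planted guide lncRNAs occupy the top five composite ranks, with a
clear score gap to the decoy binders below them. Recovery against the
ground truth:

```r
str(recovery_report(res, sim$truth))
#> List of 9
#>  $ contact_recall      : num 1
#>  $ contact_precision   : num 1
#>  $ site_recall         : num 1
#>  $ site_precision      : num 1
#>  $ guides_in_top       : int 5
#>  $ lost_enhancer_recall: num 1
#>  $ protac_lost_recall  : num 1
#>  $ deg_recovery        : num 1
#>  $ attribution_fraction: num 0.199
```

Every planted guide→enhancer contact, binding site, knockdown-lost enhancer
and loop-connected DEG is recovered; ~20% of PROTAC-lost enhancers are
attributable to the planted knockdowns, matching the planted share:

```r
res$attribution
#> $n_protac        [1] 996
#> $n_knockdown_union [1] 198
#> $n_both          [1] 198
#> $fraction        [1] 0.1987952

head(res$hubs$histogram)
#>   degree n_enhancers
#> 1      1         190
#> 2      2         199
#> 3      3         200
#> 4      4         197
#> 5      5         210
```

The hub-degree histogram (DEG promoters per lost enhancer) reproduces the
planted 1–5 loops-per-enhancer architecture.

A thin command-line wrapper over the same functions is provided at
`inst/cli/triadmap.R` (`simulate` and `run-all` subcommands) for users who
prefer driving the pipeline from a shell; `write_simulation()` exports every
simulated artifact in standard plain-text formats (FASTA, FASTQ, bedGraph,
BED/TSV, JSON).

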