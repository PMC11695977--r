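---
title: "Methods: mapping trans-acting lncRNA guidance of a chromatin remodeler"
author: "triadmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping trans-acting lncRNA guidance of a chromatin remodeler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadmap)
```

# The scientific question and the data triad

SWI/SNF (BRG1-containing) chromatin remodelers act at cell-type-specific
enhancers, but what targets the complex to those sites is largely unknown.
One candidate mechanism is guidance by *trans*-acting long non-coding RNAs:
lncRNAs that leave their site of transcription and contact distal chromatin.
Testing this requires joining three experimental views of the same molecular
triad:

* **RNA–DNA contacts** (Red-C/RedChIP-style proximity ligation): chimeric
  reads in which a fixed 37-nt bridge adapter joins a DNA fragment to the 3'
  end of an RNA. Mapping both sides yields an RNA-gene x genomic-bin contact
  map; the ChIP variant restricts contacts to those at the remodeler's
  binding sites.
* **Protein–RNA contacts** (iCLIP): per-nucleotide crosslink events over
  replicates identify which RNAs the remodeler binds directly, and where.
* **Protein–DNA binding and its perturbation** (CUT&RUN peaks under lncRNA
  knockdowns, ATAC-seq under acute PROTAC degradation of the remodeler,
  Hi-C loops, RNA-seq): which binding sites and enhancers depend on which
  lncRNA, and which genes respond.

`triadmap` implements the full analysis chain for these data, and — because
the deposited libraries are far beyond desk scale — ships a synthetic-data
generator that plants a known guide-lncRNA→enhancer architecture through all
of the above, so every stage is testable end to end against a ground-truth
manifest.

# Chimeric read processing

A chimeric read is modeled as `DNA part + bridge + RNA 5' part`. The bridge
finder scans each read for full-length occurrences of the bridge
(`AGTCGGAGCGTTGCCTATCGCATTGATGGTGCTAGGA`) and of its reverse complement,
tolerating up to 4 substitutions; `N` counts as a mismatch. Only full-length
occurrences are considered (the minimum overlap equals the bridge length),
and the reported hit is the minimum-mismatch one; ties are resolved by
smallest offset, then forward before reverse. These tie-breaks are declared
conventions: with a 37-nt pattern and ≤4 mismatches, genuine ties are
vanishingly rare on real reads, but a deterministic rule keeps the output
reproducible.

Splitting follows the adapter geometry: for a forward hit, upstream of the
bridge is the DNA part and downstream the RNA part; a reverse hit is handled
by reverse-complementing the read and applying the forward rule, so a single
code path serves both orientations. Parts shorter than 14 nt are discarded,
and a hit is only split when its mismatch count is within `0.11 x 37`
(both values follow the read-trimming conventions of the assay's standard
tool chain). Read pairs additionally require a valid RNA 3'-end mate
(`^GGG` or `CCC$`) before they can enter contact assignment.

Alignment is exposed as an interface: the built-in aligner reports a locus
only when a part (or its reverse complement) has exactly one exact,
full-length genomic occurrence, which is the correct behavior on the
synthetic random-sequence genomes. Real libraries should be aligned with a
dedicated spliced aligner and imported at the split-parts table level; the
uniqueness filter is the part of the paper-level procedure that matters
downstream, and it is preserved.

# Contact maps

Uniquely mapped DNA parts are assigned to 5-kb bins by their 5' coordinate
(a declared choice for parts straddling bin edges). A pair contributes one
count to (gene, bin) only when both RNA alignments fall in the *same*
annotated gene; when genes overlap, the longest-overlap gene wins and exact
ties drop the pair — conservative, in the spirit of unique assignment.
Counts are normalized to contacts per million valid contacts, so normalized
frequencies sum exactly to the scale and are depth-comparable. A contact is
*trans* when its bin lies on another chromosome or strictly more than 5 Mb
from the gene's interval; a gap of exactly 5 Mb is *cis*.

For in-peak versus out-of-peak frequency comparisons, a bin "contains" a
peak when any overlap exists. The significance test is a Wilcoxon
signed-rank test; because a signed-rank test needs pairs and the pairing
unit is not dictated by the assay, we pair *per RNA gene*: each gene with
contacts in both groups contributes (mean in-peak frequency, mean
out-of-peak frequency). Peak-shuffling (uniform relocation within the
chromosome, lengths preserved, non-overlapping, seeded) provides the
negative control that the enrichment is positional rather than
compositional.

# iCLIP binding sites and candidate ranking

Site calling consumes a pooled per-nucleotide score track plus per-replicate
event tracks and applies four rules in order: (1) drop the globally lowest
2% of scored positions (ties broken by coordinate so the cut is
deterministic); (2) greedily seed 7-nt sites at remaining positions in
descending score order, suppressing overlaps; (3) require at least 3
event-covered positions per site in the pooled track; (4) require events in
at least 4 of 5 replicates. The greedy order, the global (rather than
per-chromosome) percentile, and "≥1 event" (rather than "≥1 called site")
as the replicate-support unit are declared choices where the procedure
leaves room; the test-suite pins them against an exhaustive
window-enumeration oracle.

Coverage is expressed as RPKM (`events x 1e9 / (length x library)`), and
per-gene enrichment as `log2(iCLIP RPKM / RNA-seq RPKM)`, defined only when
both are positive — genes without RNA-seq signal are excluded rather than
imputed. Biotype-level site enrichment compares observed site counts per
biotype against expectations proportional to each biotype's share of the
expressed universe (CPM > 5, computed on pooled counts), with a two-sided
Fisher exact test.

Candidate lncRNAs must be present in the contact data, carry at least one
binding site, and be expressed. Four metrics — iCLIP coverage, expression,
enrichment, and site count — are each z-standardized over the full lncRNA
universe; the composite is their unweighted mean ("mean scaled value"), and
the top 16 are selected by default. z-standardization makes the four
heterogeneous scales commensurable without weighting decisions.

# Peak annotation

Genomic context uses the peak midpoint so that promoter/intronic/intergenic
labels partition any peak set; the promoter window is −1000/+100 around the
TSS, strand-aware — a common annotator default made explicit as
configuration. Chromatin-state assignment takes the state with maximal
base-pair overlap, with midpoint state as tie-break. RNA-association
classes (`none`/`cis`/`trans`/`mixed`) summarize the classes of contacts
overlapping each peak; in the end-to-end pipeline this classification uses
the confident contact set (see below) because uniform background
singletons otherwise blanket every bin and carry no positional information.
Cell-type specificity requires an enhancer-class state in the target cell
and repressed/inactive states everywhere else; the state label sets are
required configuration because they depend on the segmentation model.

# Differential binding

Replicate count matrices are normalized by reads-in-peaks (FRiP-style): each
replicate column is scaled by `mean(RiP)/RiP`. The per-peak test works on
`log2(normalized + 1)` values with an empirical-Bayes moderated t statistic
(limma, trend on abundance), followed by Benjamini–Hochberg adjustment and a
0.05 FDR threshold; direction comes from the sign of the
treatment-over-control fold change. The moderation is a deliberate design
choice: with three replicates per condition, a plain two-sample t statistic
has ~4 residual degrees of freedom, and at negative-binomial dispersion 0.1
an 8-fold loss yields p ≈ 1.5e-3 — right at the BH cutoff when a few percent
of peaks are truly lost, so recall collapses on exactly the effect sizes the
assay is designed to detect. Pooling variance information across peaks is
the standard remedy in this field for few-replicate designs and leaves the
null calibration intact (the test-suite checks the false-positive rate over
hundreds of simulated null matrices). Peaks with identical raw counts in
every sample carry no evidence and are reported with p = 1.

The pileup comparison for two-condition ATAC data is a Poisson
log-likelihood ratio: counts are scaled to the smaller sequencing depth, a
pseudocount of 1 is added, and
`LR = log10[ P(x1|x1) P(x2|x2) / P(x1|m) P(x2|m) ]` with `m = (x1+x2)/2`;
the factorial terms cancel, so the statistic is
`(x1 ln(x1/m) + x2 ln(x2/m)) / ln 10`, evaluated per peak rather than per
base — a desk-scale surrogate for bedGraph subtraction that keeps the
published decision threshold of 3.84 (the chi-squared 1-df critical value at
0.05). Both directions are reported separately as lost and gained.

# Enhancer–gene integration

The adapted activity-by-contact score of element *e* for gene *g* is
`A_e C_eg / Σ_e' A_e' C_e'g`, the normalization running over candidate
elements within ±5 Mb of the TSS (the canonical ABC window; the precise
"adapted" formula is not restated by the upstream tool, so this per-gene
normalized product is the declared interpretation — histone-modification
weighting is intentionally not implemented). Scores sum to 1 per gene before
thresholding; links survive with score strictly greater than 0.02. DEGs
require `|log2FC| ≥ 0.59`, BH-adjusted p ≤ 0.05, and mean ≥ 5 reads, all
with closed boundaries. Downstream set operations — upset-style exclusive
intersections of lost-enhancer sets, PROTAC attribution fractions, DEG hub
degrees per enhancer, and cross-perturbation concordance — are plain set
algebra over the thresholded link table, with enhancer identity carried by
exact consensus-peak coordinates across conditions.

# What the synthetic generator emulates

```{r config}
cfg <- synthetic_config(seed = 1)
str(cfg[c("n_chromosomes", "chromosome_length", "n_genes", "n_guides",
          "targets_per_guide", "n_contacts", "background_contact_fraction",
          "bridge_mutation_rate")])
```

The generator builds 3 chromosomes of 12 Mb of random sequence (scrubbed of
any accidental bridge occurrence so detection is unambiguous), places 300
non-overlapping genes with biotype proportions of 25% lncRNA, 60%
protein-coding and 5% each of snoRNA/snRNA/miRNA, and plants:

* 5 guide lncRNAs, each with 40 gene-free target bins that are
  interchromosomal or >5 Mb away — the distal-targeting architecture under
  study;
* 100,000 chimeric read pairs (70% signal, 30% uniform background; 2%
  per-base bridge substitution; reads of 2x100 nt with both parts ≥20 nt so
  splits always clear the 14-nt minimum; half the reads reverse-oriented);
* 7-nt binding sites (10 per guide, 1–3 in each of 15 weaker "decoy"
  lncRNAs) whose three central positions carry events in all five
  replicates, over expression-proportional background and sparse
  replicate-inconsistent noise;
* a consensus peak set (target enhancers at bin coordinates, PROTAC-only
  enhancers, promoter and intergenic background peaks) with
  negative-binomial replicate counts at dispersion 0.1 around mean 100,
  knockdowns dividing their planted peaks' means by 8, and equal-depth
  ATAC pileups for the PROTAC pair;
* loop tables connecting every lost enhancer to 1–5 protein-coding
  promoters on its own chromosome within 5 Mb (so planted loops respect the
  ABC window), with decoy contacts weak enough that their ABC share stays
  below 0.02 by construction; and per-condition DEG tables in which exactly
  the loop-connected genes pass the stated filters.

Where the underlying study does not state a value (contact depth, noise
levels, replicate counts, peak means), the defaults above were chosen once
as plausible desk-scale values for these assay types and are not tuned
thereafter. Each artifact draws from its own RNG stream (`seed + offset`),
so regenerating one file never perturbs another, and everything is
byte-deterministic under the master seed.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data — includes realistic sequence composition and
mappability, splicing and spliced alignment, UMI chemistry and PCR
duplication structure, sequencing-error models beyond bridge substitutions,
distance-decay in Hi-C backgrounds, and antibody efficiency differences
between replicates. Recovery rates near 1 on synthetic data certify the
correctness of the decision rules, not the expected sensitivity on real
libraries.

# Pipeline choices and degenerate inputs

```{r pipeline, eval = FALSE}
sim <- simulate_dataset(synthetic_config(seed = 42))
res <- run_pipeline(sim)
recovery_report(res, sim$truth)
```

`run_pipeline()` separates planted signal from background with a minimum
raw contact count (default 5) when forming the recovered guide→target set:
planted (gene, bin) pairs accumulate hundreds of reads while uniform
background pairs are almost all singletons, so any threshold in a wide
range separates them; 5 was fixed in advance of the recovery experiments.
Degenerate inputs are handled explicitly: empty tracks yield empty site
lists, genes with zero activity-contact mass yield no ABC links, an empty
PROTAC lost-set makes the attribution fraction an error rather than a 0/0,
and zero-length chromosomes are skipped with a warning when binning.

Problem sizes in the shipped test-suite (a 3x12-Mb genome, 8,000–100,000
read pairs, ~1,300 peaks, 500 simulated null matrices) were chosen so the
whole suite and the acceptance script each run comfortably on a single CPU;
they are the package's own testing conditions, and all statistical
thresholds are the published ones, not adjusted to the problem size.

# Known limitations

* The built-in aligner is exact-match and unspliced; real data must be
  aligned externally.
* PureCLIP-style per-nucleotide scoring is consumed, not computed; the 2%
  score filter is applied globally, which differs from a per-chromosome
  filter when score distributions vary across chromosomes.
* The moderated replicate test is a simplified stand-in for count-model
  differential-binding engines; effect-size shrinkage is not implemented.
* The ABC adaptation uses accessibility alone as activity; histone-mark
  weighting and Hi-C matrix balancing are out of scope.
* Cross-condition peak identity is by exact coordinates, which assumes a
  shared consensus peak set upstream.
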