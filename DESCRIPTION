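Package: triadmap
Title: Mapping Trans-Acting lncRNA Guidance of Chromatin Remodelers from
    RNA-DNA Contact, iCLIP and Chromatin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for inferring how trans-acting long
    non-coding RNAs target a chromatin remodeling complex to cell-type-specific
    enhancers. Implements bridge-adapter chimeric read parsing for RNA-DNA
    proximity-ligation libraries (Red-C/RedChIP style), binned contact calling
    with cis/trans classification, reproducible 7-nt iCLIP binding-site calling
    and candidate lncRNA ranking, peak annotation against chromatin-state
    segmentations, replicate-aware differential binding and a Poisson
    log-likelihood-ratio test for accessibility changes, and activity-by-contact
    enhancer-promoter linking with enhancer-hub statistics. Ships a synthetic
    multi-omic data generator with a planted ground-truth manifest so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
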