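# One small simulated dataset and pipeline run shared (lazily) across test
# files; regenerating it per file would dominate suite runtime.
.sim_cache <- new.env(parent = emptyenv())

small_config <- function() {
  synthetic_config(seed = 101, n_contacts = 8000L,
                   n_protac_only_enhancers = 150L)
}

small_sim <- function() {
  if (is.null(.sim_cache$sim)) .sim_cache$sim <- simulate_dataset(small_config())
  .sim_cache$sim
}

small_pipeline <- function() {
  if (is.null(.sim_cache$res)) .sim_cache$res <- run_pipeline(small_sim())
  .sim_cache$res
}

# A tiny deterministic annotation used by interval-logic tests.
toy_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 20000L, 5000L),
    end = c(3000L, 26000L, 9000L),
    strand = c("+", "-", "+"),
    biotype = c("lncRNA", "protein_coding", "lncRNA"),
    tss = c(1000L, 25999L, 5000L),
    length = c(2000L, 6000L, 4000L),
    stringsAsFactors = FALSE)
}
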