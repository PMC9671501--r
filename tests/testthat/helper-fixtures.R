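# Small programmatic fixtures shared across test files.

# A toy evolve-and-resequence design: one ancestor plus `n_per` lineages in
# each of two treatments, with genotypes supplied row-wise.
toy_gm <- function(geno_rows, n_per = 4, treatments = c("normal", "low_pH")) {
  ids <- c("anc", unlist(lapply(seq_along(treatments), function(ti) {
    sprintf("t%d_%d", ti, seq_len(n_per))
  })))
  geno <- do.call(rbind, geno_rows)
  storage.mode(geno) <- "integer"
  sites <- data.frame(chrom = "chr1", pos = seq_len(nrow(geno)),
                      ref = "A", alt = "C")
  gm <- genotype_matrix(sites, ids, geno)
  meta <- data.frame(
    sample_id = ids,
    is_ancestor = c(TRUE, rep(FALSE, length(ids) - 1)),
    treatment = c(NA, rep(treatments, each = n_per)),
    lineage = c(NA, ids[-1])
  )
  list(gm = gm, meta = meta)
}

# small default genome configuration used by recovery tests
small_genome_config <- function(seed = 5, ...) {
  genome_sim_config(genome_length = 2e6, n_background_sites = 300,
                    n_genes = 60, seed = seed, ...)
}
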