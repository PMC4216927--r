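# desk-scale synthetic cohorts reused across test files

small_cohort <- function(seed = 42, n_genes = 150, n_samples = 30, n_tfs = 12,
                         n_proteins = 6, rank = 3, noise_sd = 0.1, ...) {
  generate_cohort(n_genes = n_genes, n_samples = n_samples, n_tfs = n_tfs,
                  n_proteins = n_proteins, rank = rank, noise_sd = noise_sd,
                  seed = seed, ...)
}

# center a cohort the way the pipeline does (no sd filter, for speed)
centered <- function(co) {
  list(y = mean_center(co$Y, "gene"),
       p = mean_center(co$P, "protein"),
       d = co$D, labels = co$labels, truth = co$truth)
}
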