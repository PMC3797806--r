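# one small synthetic bundle shared across test files (generated once per run)
.bundle_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_chromosomes = 1, chrom_length = 1e7,
             n_coding_genes = 40, n_lncrna_per_class = 5, ...)
}

test_bundle <- function() {
  if (is.null(.bundle_cache$b)) {
    dir <- file.path(tempdir(), "lncvsd-test-bundle")
    .bundle_cache$b <- simulate_bundle(small_config(), dir)
  }
  .bundle_cache$b
}

bundle_pipeline_config <- function(b, ...) {
  pipeline_config(paths = b$paths[c("matrix", "design", "annotation", "track",
                                    "elements", "gene_sets", "ct")], ...)
}
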