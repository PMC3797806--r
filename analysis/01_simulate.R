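#!/usr/bin/env Rscript
# Generate the synthetic study bundle that stands in for the undeposited
# two-condition (VSD vs NC) lncRNA microarray experiment: genome annotation
# with six planted positional classes, expression matrix with planted
# fold-changes, conservation track with planted elements, gene sets with a
# cardiac set enriched by construction, and a five-tissue qPCR Ct table.

suppressMessages(library(lncvsd))

seed <- if (length(a <- commandArgs(TRUE)) > 0) as.integer(a[1]) else 1L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
b <- simulate_bundle(cfg, "results/bundle")

cat("Simulated study (seed", seed, "):\n")
cat(" -", cfg$n_coding_genes, "coding genes and",
    6 * cfg$n_lncrna_per_class, "lncRNAs (", cfg$n_lncrna_per_class,
    "per positional class ) on", cfg$n_chromosomes, "chromosomes\n")
cat(" -", cfg$n_replicates_per_group, "biological replicates per condition,",
    "planted |log2FC| =", cfg$planted_log2fc, ", array noise SD =",
    cfg$noise_sd, "\n")
cat(" -", length(b$truth$de_signs), "planted differential probes;",
    "candidates:", paste(b$truth$candidates, collapse = ", "), "\n")
cat(" - files:\n")
for (p in b$paths) cat("   ", p, "\n")
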