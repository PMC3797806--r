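#!/usr/bin/env Rscript
# Test gene sets for over-representation among the coding neighbors of up-
# and down-regulated lncRNAs: one-sided hypergeometric (Fisher) test with a
# chi-square companion and Benjamini-Hochberg FDR, over the neighbor-gene
# universe.

suppressMessages(library(lncvsd))

cls <- read.delim("results/classification.tsv")
up <- readLines("results/lncrna_up.txt")
down <- readLines("results/lncrna_down.txt")

ns <- neighbor_gene_sets(cls, up, down)
coll <- read_gmt("results/bundle/gene_sets.gmt", universe = ns$universe_genes)

cat("Neighbor-gene queries: ", length(ns$up_genes), "genes (up),",
    length(ns$down_genes), "genes (down), universe",
    length(coll$universe), "genes,", length(coll$sets), "sets\n\n")

for (dir in c("up", "down")) {
  q <- if (dir == "up") ns$up_genes else ns$down_genes
  if (length(q) == 0) { cat("no", dir, "query genes\n"); next }
  fis <- fisher_enrichment(q, coll)
  chi <- chi2_enrichment(q, coll)
  fis$chi2_p <- chi$p_value[match(fis$set_id, chi$set_id)]
  write.table(fis, sprintf("results/enrichment_%s.tsv", dir), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("Top sets among neighbors of", dir, "lncRNAs:\n")
  print(head(fis[, c("set_id", "k", "K", "p_value", "fdr")], 3),
        row.names = FALSE)
  cat("\n")
}
cat("Wrote results/enrichment_up.tsv, results/enrichment_down.tsv\n")
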