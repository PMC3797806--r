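#!/usr/bin/env Rscript
# Classify every profiled lncRNA into one of the six positional classes
# relative to the coding annotation, assign the nearest coding neighbor
# within 100 kb, and summarize class counts, length distribution and
# per-class neighbor distances.

suppressMessages(library(lncvsd))

ann <- read_annotation_gtf("results/bundle/annotation.gtf")
cls <- classify_lncrnas(ann)
write_classification(cls, "results/classification.tsv")

s <- summarize_context(cls, ann)
cat("Positional classes of", nrow(cls), "profiled lncRNAs:\n")
print(s$counts_by_class)
cat("\nTranscript length distribution (bp):\n")
print(s$length_histogram)
cat("\nMedian gap to the assigned coding neighbor, by class (bp):\n")
print(round(s$median_distance_by_class))
cat("\nWrote results/classification.tsv\n")
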