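#!/usr/bin/env Rscript
# Summarize phastCons-style conservation per lncRNA over exonic bases
# (conserved = score >= 0.5) and compare the per-class median scores,
# the cross-species conservation view of the dysregulated lncRNA landscape.

suppressMessages(library(lncvsd))

ann <- read_annotation_gtf("results/bundle/annotation.gtf")
track <- read_track("results/bundle/conservation.bedgraph", "bedGraph")
elements <- read_elements_bed("results/bundle/conserved_elements.bed")
cls <- read.delim("results/classification.tsv")

lnc_ids <- ann$transcripts$transcript_id[ann$transcripts$biotype == "lncRNA"]
summ <- summarize_conservation(ann, track, elements, ids = lnc_ids)
write_conservation(summ, "results/conservation.tsv")

cat("Conservation over", nrow(summ), "lncRNAs:\n")
cat(" - median conserved-base fraction:",
    round(median(summ$conserved_fraction, na.rm = TRUE), 4), "\n")
cat(" -", sum(summ$overlaps_element), "lncRNAs overlap a conserved element\n")
cat("\nPer-class median of per-transcript median phastCons score:\n")
print(round(category_median(summ, cls), 3))

# coding genes as the conserved reference category
coding_ids <- ann$transcripts$transcript_id[
  ann$transcripts$biotype == "protein_coding"]
coding_summ <- summarize_conservation(ann, track, elements, ids = coding_ids)
cat("\nCoding-gene reference: median of per-gene median scores:",
    round(median(coding_summ$median_score, na.rm = TRUE), 3),
    "vs lncRNA:", round(median(summ$median_score, na.rm = TRUE), 3), "\n")
cat("Wrote results/conservation.tsv\n")
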