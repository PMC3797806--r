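Package: lncvsd
Title: Integrated Analysis of Dysregulated Long Non-Coding RNAs in Fetal
    Hearts with Ventricular Septal Defect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of an integrated microarray analysis
    of long non-coding RNAs (lncRNAs) dysregulated in fetal cardiac tissue
    with ventricular septal defect (VSD). Provides quantile normalization and
    volcano filtering of two-condition expression matrices, positional
    classification of lncRNAs against protein-coding genes (intergenic,
    intronic antisense, natural antisense, bidirectional, exon and intron
    sense-overlapping), nearest coding-neighbor assignment within 100 kb,
    phastCons-style conservation summaries with the score >= 0.5 conserved-base
    criterion, hypergeometric gene-set enrichment of neighbor genes with
    Benjamini-Hochberg FDR, 2^-ddCt relative quantification of qPCR Ct tables,
    and the candidate-prioritization cascade combining all of the above.
    A synthetic-data generator with recorded ground truth (annotation,
    expression, conservation tracks, gene sets, Ct tables) makes every stage
    testable without access to raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
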