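# small hand-built genome used by several cases: one 10 kb coding gene with
# three exons on '+', plus distant second gene
demo_annotation <- function() {
  genes <- data.frame(
    transcript_id = c("GENEA", "GENEB"),
    chrom = "chr1",
    start = c(10000, 500000), end = c(20000, 510000),
    strand = c("+", "+"), biotype = "protein_coding")
  exons <- data.frame(
    transcript_id = c("GENEA", "GENEA", "GENEA", "GENEB", "GENEB"),
    chrom = "chr1",
    start = c(10000, 14000, 18000, 500000, 508000),
    end = c(10500, 14500, 20000, 500500, 510000),
    strand = c("+", "+", "+", "+", "+"))
  list(genes = genes, exons = exons)
}

with_lnc <- function(lnc) {
  d <- demo_annotation()
  lnc$biotype <- "lncRNA"
  ex <- lnc[c("transcript_id", "chrom", "start", "end", "strand")]
  transcript_set(rbind(d$genes, lnc), rbind(d$exons, ex))
}

classify_one <- function(lnc, ...) {
  ann <- with_lnc(lnc)
  classify_lncrnas(ann, build_index(ann), ...)
}

test_that("each positional class is recognized from its defining geometry", {
  cases <- list(
    # same strand, overlapping exon 2
    list(lnc = data.frame(transcript_id = "L", chrom = "chr1", start = 14300,
                          end = 15200, strand = "+"),
         class = "exon_sense_overlapping", nb = "GENEA", d = 0),
    # same strand, inside intron 1
    list(lnc = data.frame(transcript_id = "L", chrom = "chr1", start = 11000,
                          end = 13000, strand = "+"),
         class = "intron_sense_overlapping", nb = "GENEA", d = 0),
    # opposite strand, overlapping exon 2
    list(lnc = data.frame(transcript_id = "L", chrom = "chr1", start = 14300,
                          end = 15200, strand = "-"),
         class = "natural_antisense", nb = "GENEA", d = 0),
    # opposite strand, adjacent head-to-head (TSS gap 1, zero bases between)
    list(lnc = data.frame(transcript_id = "L", chrom = "chr1", start = 9000,
                          end = 9999, strand = "-"),
         class = "bidirectional", nb = "GENEA", d = 0),
    # opposite strand, partial overlap crossing the gene start (not
    # contained): antisense overlap is the umbrella class
    list(lnc = data.frame(transcript_id = "L", chrom = "chr1", start = 9000,
                          end = 10100, strand = "-"),
         class = "natural_antisense", nb = "GENEA", d = 0),
    # opposite strand, inside intron 1
    list(lnc = data.frame(transcript_id = "L", chrom = "chr1", start = 11000,
                          end = 13000, strand = "-"),
         class = "intronic_antisense", nb = "GENEA", d = 0),
    # head-to-head: '-' lncRNA ending 49 bp upstream of the gene TSS
    list(lnc = data.frame(transcript_id = "L", chrom = "chr1", start = 8500,
                          end = 9951, strand = "-"),
         class = "bidirectional", nb = "GENEA", d = 48),
    # nearest gene 30 kb away
    list(lnc = data.frame(transcript_id = "L", chrom = "chr1", start = 50001,
                          end = 51000, strand = "+"),
         class = "intergenic", nb = "GENEA", d = 30000),
    # beyond the 100 kb window on both sides
    list(lnc = data.frame(transcript_id = "L", chrom = "chr1", start = 300000,
                          end = 301000, strand = "+"),
         class = "intergenic", nb = NA_character_, d = NA_real_))
  for (cs in cases) {
    got <- classify_one(cs$lnc)
    expect_identical(got$positional_class, cs$class, label = cs$class)
    expect_identical(got$neighbor_gene_id, cs$nb)
    expect_equal(got$distance_bp, cs$d)
  }
})

test_that("antisense lncRNA over an exon matches the SMAD1-type geometry", {
  # antisense transcript originating 2,105 bp downstream of exon 2 and
  # spanning back across it: natural antisense with the host as neighbor
  d <- demo_annotation()
  lnc <- data.frame(transcript_id = "LSMAD", chrom = "chr1",
                    start = 14200, end = 14500 + 2105, strand = "-",
                    biotype = "lncRNA")
  ann <- transcript_set(rbind(d$genes, lnc),
                        rbind(d$exons, lnc[c("transcript_id", "chrom",
                                             "start", "end", "strand")]))
  got <- classify_lncrnas(ann)
  expect_identical(got$positional_class, "natural_antisense")
  expect_identical(got$neighbor_gene_id, "GENEA")
})

test_that("head-to-head lncRNA 49 bp from a coding TSS is bidirectional", {
  # FGF10-type geometry: '-' strand gene with TSS at its end; lncRNA on '+'
  # starting 49 bp past it
  genes <- data.frame(transcript_id = "GFGF", chrom = "chr2",
                      start = 1000, end = 9000, strand = "-",
                      biotype = "protein_coding")
  exons <- data.frame(transcript_id = c("GFGF", "GFGF"), chrom = "chr2",
                      start = c(1000, 8000), end = c(2000, 9000),
                      strand = "-")
  lnc <- data.frame(transcript_id = "LFGF", chrom = "chr2",
                    start = 9049, end = 10000, strand = "+",
                    biotype = "lncRNA")
  ann <- transcript_set(rbind(genes, lnc),
                        rbind(exons, lnc[c("transcript_id", "chrom", "start",
                                           "end", "strand")]))
  got <- classify_lncrnas(ann)
  expect_identical(got$positional_class, "bidirectional")
  expect_identical(got$neighbor_gene_id, "GFGF")
  # TSS gap 49 => 48 intervening bases
  expect_equal(got$distance_bp, 48)
})

test_that("classifier agrees with the brute-force oracle on random genomes", {
  set.seed(99)
  for (rep in 1:12) {
    ann <- random_genome(n_genes = 30, n_lnc = 25)
    got <- classify_lncrnas(ann)
    exp <- oracle_classify(ann)
    got <- got[order(got$lncrna_id), ]
    exp <- exp[order(exp$lncrna_id), ]
    expect_equal(got$positional_class, exp$positional_class)
    expect_equal(got$neighbor_gene_id, exp$neighbor_gene_id)
    expect_equal(got$distance_bp, as.integer(exp$distance_bp),
                 ignore_attr = TRUE)
  }
})

test_that("flipping lncRNA strands exchanges sense and antisense classes", {
  b <- test_bundle()
  tx <- b$annotation$transcripts
  ex <- b$annotation$exons
  is_lnc_tx <- tx$biotype == "lncRNA"
  is_lnc_ex <- ex$transcript_id %in% tx$transcript_id[is_lnc_tx]
  flip <- function(s) ifelse(s == "+", "-", "+")
  tx$strand[is_lnc_tx] <- flip(tx$strand[is_lnc_tx])
  ex$strand[is_lnc_ex] <- flip(ex$strand[is_lnc_ex])
  flipped <- transcript_set(tx, ex)
  orig <- classify_lncrnas(b$annotation)
  flp <- classify_lncrnas(flipped)
  flp <- flp[match(orig$lncrna_id, flp$lncrna_id), ]
  mapping <- c(exon_sense_overlapping = "natural_antisense",
               natural_antisense = "exon_sense_overlapping",
               intron_sense_overlapping = "intronic_antisense",
               intronic_antisense = "intron_sense_overlapping",
               # a flipped head-to-head partner is same-strand and proximal
               bidirectional = "intergenic",
               intergenic = "intergenic")
  expect_identical(flp$positional_class,
                   unname(mapping[orig$positional_class]))
})

test_that("distances are symmetric between lncRNA and neighbor gene", {
  b <- test_bundle()
  cls <- classify_lncrnas(b$annotation)
  tx <- b$annotation$transcripts
  with_nb <- cls[!is.na(cls$neighbor_gene_id), ]
  for (i in seq_len(nrow(with_nb))) {
    l <- tx[tx$transcript_id == with_nb$lncrna_id[i], ]
    g <- tx[tx$transcript_id == with_nb$neighbor_gene_id[i], ]
    expect_equal(oracle_gap(l$start, l$end, g$start, g$end),
                 oracle_gap(g$start, g$end, l$start, l$end))
    expect_equal(with_nb$distance_bp[i],
                 oracle_gap(l$start, l$end, g$start, g$end))
  }
})

test_that("empty and degenerate index queries behave as documented", {
  d <- demo_annotation()
  lnc <- data.frame(transcript_id = "L", chrom = "chrUn", start = 100,
                    end = 900, strand = "+", biotype = "lncRNA")
  ann <- transcript_set(rbind(d$genes, lnc),
                        rbind(d$exons, lnc[c("transcript_id", "chrom",
                                             "start", "end", "strand")]))
  got <- classify_lncrnas(ann)
  # chromosome absent from the coding index: intergenic, no neighbor
  expect_identical(got$positional_class, "intergenic")
  expect_true(is.na(got$neighbor_gene_id))
  # no coding genes at all
  only_lnc <- transcript_set(lnc, lnc[c("transcript_id", "chrom", "start",
                                        "end", "strand")])
  got2 <- classify_lncrnas(only_lnc, build_index(only_lnc))
  expect_identical(got2$positional_class, "intergenic")
  expect_error(transcript_set(rbind(d$genes, d$genes), rbind(d$exons, d$exons)),
               "duplicate")
})

test_that("context summaries match direct recomputation", {
  b <- test_bundle()
  cls <- classify_lncrnas(b$annotation)
  s <- summarize_context(cls, b$annotation)
  expect_equal(sum(s$counts_by_class), nrow(cls))
  expect_true(all(s$counts_by_class == 5))  # 5 planted per class
  expect_equal(sum(s$length_histogram), nrow(cls))
  for (cl in names(s$median_distance_by_class)) {
    d <- cls$distance_bp[cls$positional_class == cl & !is.na(cls$distance_bp)]
    if (length(d) > 0) {
      expect_equal(unname(s$median_distance_by_class[cl]), median(d))
    } else {
      expect_true(is.na(s$median_distance_by_class[cl]))
    }
  }
  # all-lengths-in-one-bin case
  tiny <- data.frame(transcript_id = c("l1", "l2"), chrom = "chr1",
                     start = c(100, 1000), end = c(599, 1499), strand = "+",
                     biotype = "lncRNA")
  ann <- transcript_set(tiny, tiny[c("transcript_id", "chrom", "start",
                                     "end", "strand")])
  cls2 <- classify_lncrnas(ann, build_index(ann))
  s2 <- summarize_context(cls2, ann)
  expect_equal(unname(s2$length_histogram["[200,1000)"]), 2L,
               ignore_attr = TRUE)
})
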