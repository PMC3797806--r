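make_track <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr)$score <- df$score
  lncvsd:::new_conservation_track(gr)
}

one_tx <- function(start = 101, end = 200, exons = NULL) {
  tx <- data.frame(transcript_id = "T1", chrom = "chr1", start = start,
                   end = end, strand = "+", biotype = "lncRNA")
  if (is.null(exons))
    exons <- tx[c("transcript_id", "chrom", "start", "end", "strand")]
  transcript_set(tx, exons)
}

test_that("fixedStep WIG positions follow the format definition", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "0.1", "0.9"), f)
  tr <- read_track(f, "fixedStep_wig")
  df <- as.data.frame(tr$ranges)
  expect_equal(GenomicRanges::start(GenomicRanges::reduce(tr$ranges)), 1)
  expect_equal(sum(GenomicRanges::width(tr$ranges)), 2)
  expect_equal(sort(df$score), c(0.1, 0.9))
  # empty file -> empty track
  f2 <- withr::local_tempfile(fileext = ".wig")
  writeLines(character(0), f2)
  expect_length(read_track(f2, "fixedStep_wig")$ranges, 0)
})

test_that("track write/read round-trips losslessly in both formats", {
  df <- data.frame(chrom = "chr1", start = c(11, 51, 200), end = c(20, 60, 203),
                   score = c(0.25, 0.75, 0.5))
  tr <- make_track(df)
  for (fmt in c("fixedStep_wig", "bedGraph")) {
    f <- withr::local_tempfile()
    write_track(tr, f, format = fmt)
    back <- read_track(f, fmt)
    # per-base content identical regardless of run segmentation
    a <- one_tx(1, 300)
    expect_equal(summarize_conservation(a, back)[-1],
                 summarize_conservation(a, tr)[-1])
  }
  expect_error(make_track(data.frame(chrom = "chr1", start = 1, end = 2,
                                     score = 1.5)), "\\[0, 1\\]")
})

test_that("transcript summaries honor the inclusive 0.5 conservation criterion", {
  a <- one_tx(101, 200)
  uniform <- make_track(data.frame(chrom = "chr1", start = 101, end = 200,
                                   score = 0.7))
  s <- summarize_conservation(a, uniform)
  expect_equal(s$n_bases_covered, 100)
  expect_equal(s$median_score, 0.7)
  expect_equal(s$conserved_fraction, 1.0)

  boundary <- make_track(data.frame(chrom = "chr1", start = 101, end = 200,
                                    score = 0.5))
  expect_equal(summarize_conservation(a, boundary)$conserved_fraction, 1.0)
  below <- make_track(data.frame(chrom = "chr1", start = 101, end = 200,
                                 score = 0.4999))
  expect_equal(summarize_conservation(a, below)$conserved_fraction, 0)

  # uncovered transcript: flagged, not scored zero
  far <- one_tx(5000, 5100)
  s0 <- summarize_conservation(far, uniform)
  expect_equal(s0$n_bases_covered, 0)
  expect_true(is.na(s0$median_score))
})

test_that("summaries match a base-by-base oracle and ignore chunk boundaries", {
  set.seed(31)
  for (rep in 1:5) {
    n_runs <- 8
    starts <- sort(sample(seq(1, 400, by = 10), n_runs))
    df <- data.frame(chrom = "chr1", start = starts,
                     end = starts + sample(3:9, n_runs, replace = TRUE),
                     score = round(runif(n_runs), 3))
    df$end <- pmin(df$end, c(df$start[-1] - 1, 1000))  # keep disjoint
    df <- df[df$end >= df$start, ]
    exdf <- data.frame(transcript_id = "T1", chrom = "chr1",
                       start = c(5, 150), end = c(120, 320), strand = "+")
    a <- one_tx(5, 320, exons = exdf)
    s <- summarize_conservation(a, make_track(df))
    o <- oracle_conservation(df, exdf)
    expect_equal(s$n_bases_covered, o$n)
    expect_equal(s$median_score, o$median)
    expect_equal(s$conserved_fraction, o$frac)

    # split every run in two: summaries unchanged
    half <- floor((df$start + df$end) / 2)
    keep <- df$end > df$start
    split_df <- rbind(
      data.frame(chrom = df$chrom, start = df$start, end = half,
                 score = df$score)[keep, ],
      data.frame(chrom = df$chrom, start = half + 1, end = df$end,
                 score = df$score)[keep, ],
      df[!keep, ])
    s2 <- summarize_conservation(a, make_track(split_df))
    expect_equal(s2[-1], s[-1])
  }
})

test_that("conserved fraction is monotone in the score threshold", {
  # implied by construction; checked via explicit recount at several cuts
  set.seed(8)
  df <- data.frame(chrom = "chr1", start = seq(1, 991, by = 10),
                   end = seq(10, 1000, by = 10),
                   score = round(runif(100), 3))
  exdf <- data.frame(transcript_id = "T1", chrom = "chr1", start = 1,
                     end = 1000, strand = "+")
  fracs <- vapply(c(0.2, 0.5, 0.8), function(thr) {
    covered <- rep(df$score, df$end - df$start + 1)
    mean(covered >= thr)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("category medians equal direct recomputation and respect bounds", {
  summaries <- data.frame(transcript_id = c("a", "b", "c", "d"),
                          n_bases_covered = c(10, 10, 10, 0),
                          median_score = c(0.1, 0.2, 0.9, NA),
                          conserved_fraction = c(0, 0, 1, NA),
                          overlaps_element = FALSE)
  classified <- data.frame(lncrna_id = c("a", "b", "c", "d"),
                           positional_class = c("intergenic", "intergenic",
                                                "intergenic", "bidirectional"),
                           neighbor_gene_id = NA, distance_bp = NA)
  cm <- category_median(summaries, classified)
  expect_equal(unname(cm["intergenic"]), 0.2)
  expect_true(is.na(cm["bidirectional"]))       # only an uncovered member
  expect_true(is.na(cm["natural_antisense"]))   # empty class
  covered <- summaries$median_score[summaries$n_bases_covered > 0]
  expect_gte(cm["intergenic"], min(covered))
  expect_lte(cm["intergenic"], max(covered))
})

test_that("conservation filter keeps order, applies threshold, errors on unknowns", {
  summaries <- data.frame(transcript_id = c("x", "y", "z"),
                          n_bases_covered = 10,
                          median_score = 0.5,
                          conserved_fraction = c(1, 0, 0.5),
                          overlaps_element = TRUE)
  expect_identical(conservation_filter(c("z", "x", "y"), summaries, 0),
                   c("z", "x", "y"))
  expect_identical(conservation_filter(c("z", "x", "y"), summaries, 0.5),
                   c("z", "x"))
  expect_identical(conservation_filter(c("x"), summaries, 1), "x")
  expect_error(conservation_filter(c("x", "nope"), summaries, 0.5), "nope")
})

test_that("planted conserved elements are recovered through the file interface", {
  b <- test_bundle()
  tr <- read_track(b$paths$track, "bedGraph")
  el <- read_elements_bed(b$paths$elements)
  s <- summarize_conservation(b$annotation, tr, el)
  truth <- unlist(b$truth$conserved_fraction)
  got <- s$conserved_fraction[match(names(truth), s$transcript_id)]
  got[is.na(got)] <- 0
  expect_equal(got, unname(truth), tolerance = 1e-12)
  # elements imply overlap flags
  expect_true(all(s$overlaps_element[s$conserved_fraction > 0]))
})
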