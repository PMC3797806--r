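#' Transcript annotation container
#'
#' A `transcript_set` holds stranded, exon-resolved transcript models for
#' protein-coding genes and lncRNAs on a common genome. Coordinates are
#' 1-based closed throughout (the GTF/GRanges convention); BED and WIG inputs
#' are converted at the reader boundary.
#'
#' @param transcripts data.frame with columns `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` ("+"/"-") and `biotype`
#'   ("protein_coding"/"lncRNA").
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`; exons of a transcript must be sorted, non-overlapping
#'   and contained in the transcript span.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, exons) {
  need_tx <- c("transcript_id", "chrom", "start", "end", "strand", "biotype")
  need_ex <- c("transcript_id", "chrom", "start", "end", "strand")
  stopifnot(all(need_tx %in% names(transcripts)), all(need_ex %in% names(exons)))
  transcripts <- as.data.frame(transcripts)[need_tx]
  exons <- as.data.frame(exons)[need_ex]
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript ids in annotation")
  if (any(transcripts$start > transcripts$end))
    stop("transcript with start > end")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(transcripts$biotype %in% c("protein_coding", "lncRNA")))
    stop("biotype must be 'protein_coding' or 'lncRNA'")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("exon refers to unknown transcript")
  # exon containment / ordering checks
  sp <- split(exons, exons$transcript_id)
  tx <- transcripts[match(names(sp), transcripts$transcript_id), ]
  for (i in seq_along(sp)) {
    e <- sp[[i]][order(sp[[i]]$start), ]
    if (any(e$start > e$end)) stop("exon with start > end in ", names(sp)[i])
    if (any(e$start < tx$start[i]) || any(e$end > tx$end[i]))
      stop("exon outside transcript span in ", names(sp)[i])
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping exons in ", names(sp)[i])
  }
  if (!all(transcripts$transcript_id %in% exons$transcript_id))
    stop("transcript without exons")
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  n <- table(factor(x$transcripts$biotype,
                    levels = c("protein_coding", "lncRNA")))
  cat("transcript_set:", n[["protein_coding"]], "coding,",
      n[["lncRNA"]], "lncRNA transcripts;",
      nrow(x$exons), "exons on",
      length(unique(x$transcripts$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Subset a transcript_set by biotype
#' @param x a `transcript_set`
#' @param biotype "protein_coding" or "lncRNA"
#' @return a `transcript_set` with only the requested biotype
#' @export
subset_biotype <- function(x, biotype) {
  stopifnot(inherits(x, "transcript_set"))
  keep <- x$transcripts$biotype == biotype
  ids <- x$transcripts$transcript_id[keep]
  transcript_set(x$transcripts[keep, , drop = FALSE],
                 x$exons[x$exons$transcript_id %in% ids, , drop = FALSE])
}

## GRanges views -------------------------------------------------------------

tx_granges <- function(x, biotype = NULL) {
  tx <- x$transcripts
  if (!is.null(biotype)) tx <- tx[tx$biotype == biotype, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(tx$start, tx$end),
    strand = tx$strand)
  S4Vectors::mcols(gr)$transcript_id <- tx$transcript_id
  S4Vectors::mcols(gr)$biotype <- tx$biotype
  gr
}

exon_granges <- function(x, biotype = NULL) {
  ex <- x$exons
  if (!is.null(biotype)) {
    ids <- x$transcripts$transcript_id[x$transcripts$biotype == biotype]
    ex <- ex[ex$transcript_id %in% ids, , drop = FALSE]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand)
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  gr
}

## GTF I/O -------------------------------------------------------------------

#' Write a transcript_set as GTF
#'
#' Emits one `transcript` and one `exon` feature per interval with
#' `gene_id`, `transcript_id` and `gene_biotype` attributes. Each transcript
#' is its own gene for the purposes of this file (the array profiles
#' transcripts, not gene models).
#'
#' @param x a `transcript_set`
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(x, path) {
  stopifnot(inherits(x, "transcript_set"))
  tx <- x$transcripts
  ex <- x$exons
  feat <- rbind(
    data.frame(chrom = tx$chrom, type = "transcript", start = tx$start,
               end = tx$end, strand = tx$strand, id = tx$transcript_id,
               biotype = tx$biotype, stringsAsFactors = FALSE),
    data.frame(chrom = ex$chrom, type = "exon", start = ex$start,
               end = ex$end, strand = ex$strand, id = ex$transcript_id,
               biotype = tx$biotype[match(ex$transcript_id, tx$transcript_id)],
               stringsAsFactors = FALSE))
  feat <- feat[order(feat$chrom, feat$start, feat$id, feat$type != "transcript"), ]
  gr <- GenomicRanges::GRanges(feat$chrom, IRanges::IRanges(feat$start, feat$end),
                               strand = feat$strand)
  S4Vectors::mcols(gr)$source <- "lncvsd"
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$gene_id <- feat$id
  S4Vectors::mcols(gr)$transcript_id <- feat$id
  S4Vectors::mcols(gr)$gene_biotype <- feat$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF file into a transcript_set
#'
#' Transcript spans are taken from `transcript` features when present,
#' otherwise inferred as the exon hull per `transcript_id`. Coding vs lncRNA
#' status comes from the `gene_biotype` (or `transcript_biotype`/`gene_type`)
#' attribute; "protein_coding" is coding, everything else is treated as
#' lncRNA.
#'
#' @param path GTF file path
#' @return a `transcript_set`
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  bt_col <- intersect(c("gene_biotype", "transcript_biotype", "gene_type"),
                      names(mc))
  if (length(bt_col) == 0) stop("GTF lacks a gene_biotype attribute")
  biotype <- as.character(mc[[bt_col[1]]])
  biotype <- ifelse(biotype == "protein_coding", "protein_coding", "lncRNA")
  tid <- as.character(mc$transcript_id)
  is_ex <- as.character(mc$type) == "exon"
  ex <- data.frame(
    transcript_id = tid[is_ex],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_ex],
    start = GenomicRanges::start(gr)[is_ex],
    end = GenomicRanges::end(gr)[is_ex],
    strand = as.character(GenomicRanges::strand(gr))[is_ex],
    stringsAsFactors = FALSE)
  is_tx <- as.character(mc$type) == "transcript"
  if (any(is_tx)) {
    tx <- data.frame(
      transcript_id = tid[is_tx],
      chrom = as.character(GenomicRanges::seqnames(gr))[is_tx],
      start = GenomicRanges::start(gr)[is_tx],
      end = GenomicRanges::end(gr)[is_tx],
      strand = as.character(GenomicRanges::strand(gr))[is_tx],
      biotype = biotype[is_tx],
      stringsAsFactors = FALSE)
  } else {
    agg_s <- tapply(ex$start, ex$transcript_id, min)
    agg_e <- tapply(ex$end, ex$transcript_id, max)
    first <- ex[!duplicated(ex$transcript_id), ]
    tx <- data.frame(
      transcript_id = first$transcript_id,
      chrom = first$chrom,
      start = as.integer(agg_s[first$transcript_id]),
      end = as.integer(agg_e[first$transcript_id]),
      strand = first$strand,
      biotype = biotype[is_ex][!duplicated(ex$transcript_id)],
      stringsAsFactors = FALSE)
  }
  ex <- ex[order(ex$transcript_id, ex$start), ]
  transcript_set(tx, ex)
}

## Small interval helpers shared across modules ------------------------------

# gap between two closed intervals; 0 when they overlap or are adjacent
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
}
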