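#' Positional classification of lncRNAs against coding genes
#'
#' Each lncRNA is assigned to one of six positional classes relative to the
#' protein-coding annotation, mirroring the standard array-vendor taxonomy:
#'
#' * `exon_sense_overlapping` — same strand, >= 1 bp overlap with a coding exon
#' * `intron_sense_overlapping` — same strand, contained in a coding gene span
#'   with zero exonic overlap
#' * `natural_antisense` — opposite strand, overlapping a coding gene either
#'   exonically or partially (not contained)
#' * `intronic_antisense` — opposite strand, contained in a coding gene span
#'   with zero exonic overlap
#' * `bidirectional` — opposite strand, no overlap, TSS-to-TSS gap <=
#'   `bidirectional_gap_bp`
#' * `intergenic` — none of the above
#'
#' Rules are applied in that precedence order (most specific evidence wins:
#' exonic before intronic, overlap before proximity). The neighbor gene is
#' the overlapping gene for overlap classes (distance 0), the TSS partner for
#' bidirectional lncRNAs, and otherwise the nearest coding gene with a gap
#' strictly below `window_bp` (none if absent). Distances are gaps in bp
#' (adjacent intervals have gap 0); nearest-neighbor ties break toward the
#' 5' gene on the lncRNA's strand.
#'
#' @name classify
NULL

POSITIONAL_CLASSES <- c("intergenic", "intronic_antisense", "natural_antisense",
                        "bidirectional", "exon_sense_overlapping",
                        "intron_sense_overlapping")

#' Build an interval index over coding transcripts
#'
#' @param annotation a `transcript_set`; only its protein-coding transcripts
#'   enter the index.
#' @return an object of class `coding_index` supporting overlap and nearest
#'   queries.
#' @export
build_index <- function(annotation) {
  stopifnot(inherits(annotation, "transcript_set"))
  tx <- annotation$transcripts
  coding <- tx[tx$biotype == "protein_coding", , drop = FALSE]
  if (anyDuplicated(coding$transcript_id)) stop("duplicate transcript ids")
  ids <- coding$transcript_id
  genes <- GenomicRanges::GRanges(coding$chrom,
                                  IRanges::IRanges(coding$start, coding$end),
                                  strand = coding$strand)
  S4Vectors::mcols(genes)$gene_id <- ids
  ex <- annotation$exons[annotation$exons$transcript_id %in% ids, , drop = FALSE]
  exons <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end),
                                  strand = ex$strand)
  S4Vectors::mcols(exons)$gene_id <- ex$transcript_id
  tss <- ifelse(coding$strand == "+", coding$start, coding$end)
  structure(list(genes = genes, exons = exons, gene_ids = ids, tss = tss),
            class = "coding_index")
}

#' @export
print.coding_index <- function(x, ...) {
  cat("coding_index:", length(x$genes), "coding genes,",
      length(x$exons), "exons\n")
  invisible(x)
}

# pair table (lnc row index, gene index) from a Hits object; `map` translates
# subject hits to gene indices (for exon hits)
.pairs <- function(hits, map = NULL) {
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (!is.null(map)) s <- map[s]
  unique(data.frame(lnc = q, gene = s))
}

#' Classify all lncRNAs of an annotation
#'
#' @param annotation a `transcript_set` (its lncRNA transcripts are
#'   classified) or a `transcript_set` of lncRNAs only.
#' @param index a `coding_index` from [build_index()]. Defaults to an index
#'   built from `annotation` itself.
#' @param window_bp maximum gap (strict, bp) for nearest-neighbor assignment;
#'   default 100 kb.
#' @param bidirectional_gap_bp maximum TSS-to-TSS distance (bp) for the
#'   bidirectional class; default 1000.
#' @return data.frame with columns `lncrna_id`, `positional_class`,
#'   `neighbor_gene_id` (NA when none) and `distance_bp` (NA when no
#'   neighbor).
#' @export
classify_lncrnas <- function(annotation, index = build_index(annotation),
                             window_bp = 100000L,
                             bidirectional_gap_bp = 1000L) {
  stopifnot(inherits(annotation, "transcript_set"),
            inherits(index, "coding_index"))
  lnc <- annotation$transcripts
  lnc <- lnc[lnc$biotype == "lncRNA", , drop = FALSE]
  n <- nrow(lnc)
  out <- data.frame(lncrna_id = lnc$transcript_id,
                    positional_class = rep("intergenic", n),
                    neighbor_gene_id = rep(NA_character_, n),
                    distance_bp = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (n == 0 || length(index$genes) == 0) return(out)

  lv <- union(unique(lnc$chrom),
              GenomeInfoDb::seqlevels(index$genes))
  lncGR <- GenomicRanges::GRanges(factor(lnc$chrom, levels = lv),
                                  IRanges::IRanges(lnc$start, lnc$end),
                                  strand = lnc$strand)
  lncOpp <- lncGR
  GenomicRanges::strand(lncOpp) <-
    ifelse(as.character(GenomicRanges::strand(lncGR)) == "+", "-", "+")
  genes <- index$genes
  exons <- index$exons
  GenomeInfoDb::seqlevels(genes) <- lv
  GenomeInfoDb::seqlevels(exons) <- lv
  exon_gene <- match(S4Vectors::mcols(exons)$gene_id, index$gene_ids)

  ss_exon <- .pairs(GenomicRanges::findOverlaps(lncGR, exons), exon_gene)
  ss_within <- .pairs(GenomicRanges::findOverlaps(lncGR, genes, type = "within"))
  os_span <- .pairs(GenomicRanges::findOverlaps(lncOpp, genes))
  os_exon <- .pairs(GenomicRanges::findOverlaps(lncOpp, exons), exon_gene)
  os_within <- .pairs(GenomicRanges::findOverlaps(lncOpp, genes, type = "within"))

  key <- function(p) paste(p$lnc, p$gene)
  os_span$exonic <- key(os_span) %in% key(os_exon)
  os_span$within <- key(os_span) %in% key(os_within)

  assigned <- rep(FALSE, n)
  pick_min_id <- function(pairs) {
    # deterministic neighbor: lexicographically smallest qualifying gene id
    ids <- index$gene_ids[pairs$gene]
    stats::aggregate(list(id = ids), by = list(lnc = pairs$lnc),
                     FUN = function(v) sort(v)[1])
  }
  set_overlap_class <- function(pairs, class_name) {
    pairs <- pairs[!assigned[pairs$lnc], , drop = FALSE]
    if (nrow(pairs) == 0) return(invisible())
    sel <- pick_min_id(pairs)
    out$positional_class[sel$lnc] <<- class_name
    out$neighbor_gene_id[sel$lnc] <<- sel$id
    out$distance_bp[sel$lnc] <<- 0L
    assigned[sel$lnc] <<- TRUE
  }

  set_overlap_class(ss_exon, "exon_sense_overlapping")
  set_overlap_class(ss_within, "intron_sense_overlapping")
  nat <- os_span[os_span$exonic | !os_span$within, c("lnc", "gene")]
  set_overlap_class(nat, "natural_antisense")
  ia <- os_span[os_span$within & !os_span$exonic, c("lnc", "gene")]
  set_overlap_class(ia, "intronic_antisense")

  # bidirectional: opposite-strand TSS partners within the gap, spans disjoint
  lnc_tss_pos <- ifelse(lnc$strand == "+", lnc$start, lnc$end)
  tss_win <- GenomicRanges::GRanges(
    factor(lnc$chrom, levels = lv),
    IRanges::IRanges(pmax(1L, lnc_tss_pos - bidirectional_gap_bp),
                     lnc_tss_pos + bidirectional_gap_bp),
    strand = ifelse(lnc$strand == "+", "-", "+"))
  gene_tss <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(genes)),
    IRanges::IRanges(index$tss, width = 1L),
    strand = GenomicRanges::strand(genes))
  GenomeInfoDb::seqlevels(gene_tss) <- lv
  bid <- .pairs(GenomicRanges::findOverlaps(tss_win, gene_tss))
  if (nrow(bid) > 0) {
    bid <- bid[!(key(bid) %in% key(os_span)), , drop = FALSE]  # no overlap
    bid <- bid[!assigned[bid$lnc], , drop = FALSE]
  }
  if (nrow(bid) > 0) {
    bid$tss_gap <- abs(lnc_tss_pos[bid$lnc] - index$tss[bid$gene])
    bid$id <- index$gene_ids[bid$gene]
    bid <- bid[order(bid$lnc, bid$tss_gap, bid$id), ]
    bid <- bid[!duplicated(bid$lnc), ]
    out$positional_class[bid$lnc] <- "bidirectional"
    out$neighbor_gene_id[bid$lnc] <- bid$id
    out$distance_bp[bid$lnc] <- interval_gap(
      lnc$start[bid$lnc], lnc$end[bid$lnc],
      GenomicRanges::start(genes)[bid$gene],
      GenomicRanges::end(genes)[bid$gene])
    assigned[bid$lnc] <- TRUE
  }

  # intergenic: nearest coding gene with gap strictly below the window
  rest <- which(!assigned)
  if (length(rest) > 0) {
    near <- GenomicRanges::nearest(lncGR[rest], genes, select = "all",
                                   ignore.strand = TRUE)
    np <- data.frame(lnc = rest[S4Vectors::queryHits(near)],
                     gene = S4Vectors::subjectHits(near))
    if (nrow(np) > 0) {
      np$dist <- interval_gap(lnc$start[np$lnc], lnc$end[np$lnc],
                              GenomicRanges::start(genes)[np$gene],
                              GenomicRanges::end(genes)[np$gene])
      np <- np[np$dist < window_bp, , drop = FALSE]
    }
    if (nrow(np) > 0) {
      # tie-break toward the 5' gene on the lncRNA's strand
      gstart <- GenomicRanges::start(genes)[np$gene]
      gend <- GenomicRanges::end(genes)[np$gene]
      five_prime_key <- ifelse(lnc$strand[np$lnc] == "+", gstart, -gend)
      np$id <- index$gene_ids[np$gene]
      np <- np[order(np$lnc, np$dist, five_prime_key, np$id), ]
      np <- np[!duplicated(np$lnc), ]
      out$neighbor_gene_id[np$lnc] <- np$id
      out$distance_bp[np$lnc] <- np$dist
    }
  }
  out
}

#' Classify a single lncRNA transcript
#'
#' @param lncrna one-row data.frame (or list) with `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`; exons default to the full span.
#' @param index a `coding_index`
#' @inheritParams classify_lncrnas
#' @return one-row classification data.frame (see [classify_lncrnas()]).
#' @export
classify_lncrna <- function(lncrna, index, window_bp = 100000L,
                            bidirectional_gap_bp = 1000L) {
  lncrna <- as.data.frame(as.list(lncrna)[c("transcript_id", "chrom", "start",
                                            "end", "strand")])
  lncrna$biotype <- "lncRNA"
  ann <- transcript_set(lncrna, cbind(lncrna[c("transcript_id", "chrom",
                                               "start", "end", "strand")]))
  classify_lncrnas(ann, index, window_bp = window_bp,
                   bidirectional_gap_bp = bidirectional_gap_bp)
}

#' Summaries of the classified lncRNA landscape
#'
#' Produces class counts, a transcript-length histogram (bins in bp:
#' `[<1000)`, `[1000,2000)`, `[2000,3000)`, `[3000,5000)`, `>=5000`) and the
#' per-class median gap to the assigned neighbor gene.
#'
#' @param classified data.frame from [classify_lncrnas()]
#' @param annotation the `transcript_set` the classification was computed on
#' @return list with `counts_by_class`, `length_histogram`,
#'   `median_distance_by_class`.
#' @export
summarize_context <- function(classified, annotation) {
  stopifnot(inherits(annotation, "transcript_set"))
  tx <- annotation$transcripts
  len <- (tx$end - tx$start + 1L)[match(classified$lncrna_id,
                                        tx$transcript_id)]
  if (anyNA(len)) stop("classified transcript missing from annotation")
  counts <- table(factor(classified$positional_class,
                         levels = POSITIONAL_CLASSES))
  breaks <- c(0, 1000, 2000, 3000, 5000, Inf)
  labs <- c("[200,1000)", "[1000,2000)", "[2000,3000)", "[3000,5000)", ">=5000")
  hist <- table(cut(len, breaks = breaks, labels = labs, right = FALSE))
  med <- vapply(POSITIONAL_CLASSES, function(cl) {
    d <- classified$distance_bp[classified$positional_class == cl &
                                  !is.na(classified$distance_bp)]
    if (length(d) == 0) NA_real_ else stats::median(d)
  }, numeric(1))
  list(counts_by_class = counts, length_histogram = hist,
       median_distance_by_class = med)
}

#' Write a classification table as TSV
#' @param classified data.frame from [classify_lncrnas()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_classification <- function(classified, path) {
  utils::write.table(classified, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
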