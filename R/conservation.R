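#' Conservation tracks and per-transcript summaries
#'
#' phastCons-style tracks assign each covered base a score in \[0, 1\],
#' interpretable as the probability that the base lies in a conserved
#' element. A base counts as conserved when its score is at least 0.5
#' (inclusive). Per-transcript statistics are computed over exonic bases
#' covered by the track; uncovered bases are excluded from denominators
#' rather than scored zero, so "unaligned" is distinguished from
#' "unconserved".
#'
#' @name conservation
NULL

new_conservation_track <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  sc <- S4Vectors::mcols(gr)$score
  if (length(gr) > 0 && (anyNA(sc) || any(sc < 0) || any(sc > 1)))
    stop("conservation scores must lie in [0, 1]")
  if (length(gr) > 1 &&
      sum(GenomicRanges::width(GenomicRanges::reduce(gr, min.gapwidth = 0L))) <
        sum(GenomicRanges::width(gr)))
    stop("conservation track has overlapping intervals")
  structure(list(ranges = gr), class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat("conservation_track:", length(x$ranges), "runs covering",
      sum(GenomicRanges::width(x$ranges)), "bases\n")
  invisible(x)
}

#' Read a conservation track
#'
#' @param path file path
#' @param format "fixedStep_wig" or "bedGraph"
#' @return a `conservation_track`
#' @export
read_track <- function(path, format = c("fixedStep_wig", "bedGraph")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (!any(nzchar(trimws(lines)))) {
    return(new_conservation_track(
      GenomicRanges::GRanges(score = numeric(0))))
  }
  fmt <- if (format == "fixedStep_wig") "wig" else "bedGraph"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop("failed to parse ", format,
                                          " track '", path, "': ",
                                          conditionMessage(e)))
  new_conservation_track(gr)
}

#' Write a conservation track
#'
#' `fixedStep_wig` writes one value per base in fixedStep blocks (step 1);
#' `bedGraph` writes one 0-based half-open interval per run.
#'
#' @param track a `conservation_track`
#' @param path output file path
#' @param format "fixedStep_wig" or "bedGraph"
#' @return `path`, invisibly
#' @export
write_track <- function(track, path, format = c("fixedStep_wig", "bedGraph")) {
  format <- match.arg(format)
  gr <- track$ranges
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  sc <- S4Vectors::mcols(gr)$score
  if (format == "bedGraph") {
    lines <- sprintf("%s\t%d\t%d\t%s", chrom, s - 1L, e,
                     format(sc, trim = TRUE, scientific = FALSE))
    writeLines(lines, path)
    return(invisible(path))
  }
  # fixedStep: expand runs to per-base values, one block per contiguous run
  con <- file(path, "w")
  on.exit(close(con))
  if (length(gr) > 0) {
    w <- e - s + 1L
    pos <- rep.int(s, w) + sequence(w) - 1L
    val <- rep.int(sc, w)
    chr <- rep.int(chrom, w)
    new_block <- c(TRUE, diff(pos) != 1L | chr[-1] != chr[-length(chr)])
    block <- cumsum(new_block)
    starts <- pos[new_block]
    chrs <- chr[new_block]
    vals <- split(format(val, trim = TRUE, scientific = FALSE), block)
    for (b in seq_along(starts)) {
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                         chrs[b], starts[b]), con)
      writeLines(vals[[b]], con)
    }
  }
  invisible(path)
}

#' Read conserved-element intervals from BED
#' @param path BED file (0-based half-open; converted on read)
#' @return GRanges of elements
#' @export
read_elements_bed <- function(path) {
  lines <- readLines(path)
  if (!any(nzchar(trimws(lines)))) return(GenomicRanges::GRanges())
  rtracklayer::import(path, format = "bed")
}

# weighted median equal to median of the base-expanded score vector
weighted_median_bases <- function(score, w) {
  o <- order(score)
  score <- score[o]; w <- w[o]
  m <- sum(w)
  cum <- cumsum(w)
  if (m %% 2 == 1) {
    score[which(cum >= (m + 1) / 2)[1]]
  } else {
    v1 <- score[which(cum >= m / 2)[1]]
    v2 <- score[which(cum >= m / 2 + 1)[1]]
    (v1 + v2) / 2
  }
}

#' Per-transcript conservation summaries
#'
#' Statistics over exonic bases covered by the track: number of covered
#' bases, median score, conserved-base fraction (score >= 0.5, boundary
#' inclusive) and whether any exonic base overlaps a conserved element.
#'
#' @param annotation a `transcript_set`
#' @param track a `conservation_track`
#' @param elements optional GRanges of conserved elements (or NULL)
#' @param ids transcripts to summarize (default: all in `annotation`)
#' @return data.frame with `transcript_id`, `n_bases_covered`,
#'   `median_score` (NA when nothing covered), `conserved_fraction`,
#'   `overlaps_element`.
#' @export
summarize_conservation <- function(annotation, track, elements = NULL,
                                   ids = NULL) {
  stopifnot(inherits(annotation, "transcript_set"),
            inherits(track, "conservation_track"))
  if (is.null(ids)) ids <- annotation$transcripts$transcript_id
  ex <- annotation$exons[annotation$exons$transcript_id %in% ids, , drop = FALSE]
  exGR <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  tr <- track$ranges
  lv <- union(unique(ex$chrom), GenomeInfoDb::seqlevels(tr))
  GenomeInfoDb::seqlevels(exGR) <- lv
  GenomeInfoDb::seqlevels(tr) <- lv
  hits <- GenomicRanges::findOverlaps(exGR, tr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(exGR)[q], GenomicRanges::ranges(tr)[sj]))
  sc <- S4Vectors::mcols(tr)$score[sj]
  txid <- ex$transcript_id[q]

  out <- data.frame(transcript_id = ids,
                    n_bases_covered = 0L,
                    median_score = NA_real_,
                    conserved_fraction = NA_real_,
                    overlaps_element = FALSE,
                    stringsAsFactors = FALSE)
  if (length(q) > 0) {
    sp <- split(seq_along(q), txid)
    for (id in names(sp)) {
      i <- sp[[id]]
      row <- match(id, out$transcript_id)
      n <- sum(ow[i])
      out$n_bases_covered[row] <- n
      out$median_score[row] <- weighted_median_bases(sc[i], ow[i])
      out$conserved_fraction[row] <- sum(ow[i][sc[i] >= 0.5]) / n
    }
  }
  if (!is.null(elements) && length(elements) > 0) {
    el <- elements
    GenomeInfoDb::seqlevels(el) <- union(lv, GenomeInfoDb::seqlevels(el))
    GenomeInfoDb::seqlevels(exGR) <- GenomeInfoDb::seqlevels(el)
    eh <- GenomicRanges::findOverlaps(exGR, el, ignore.strand = TRUE)
    hit_ids <- unique(ex$transcript_id[S4Vectors::queryHits(eh)])
    out$overlaps_element <- out$transcript_id %in% hit_ids
  }
  out
}

#' Conservation summary for a single transcript
#' @param annotation a `transcript_set` containing the transcript
#' @param transcript_id the transcript to summarize
#' @inheritParams summarize_conservation
#' @return one-row summary data.frame
#' @export
summarize_transcript <- function(annotation, transcript_id, track,
                                 elements = NULL) {
  summarize_conservation(annotation, track, elements, ids = transcript_id)
}

#' Median of per-transcript median scores by positional class
#'
#' @param summaries data.frame from [summarize_conservation()]
#' @param classified data.frame from [classify_lncrnas()]
#' @return named numeric vector over positional classes (NA for classes with
#'   no covered transcript).
#' @export
category_median <- function(summaries, classified) {
  cls <- classified$positional_class[match(summaries$transcript_id,
                                           classified$lncrna_id)]
  if (anyNA(cls)) stop("summarized transcript missing from classification")
  vapply(POSITIONAL_CLASSES, function(cl) {
    v <- summaries$median_score[cls == cl & summaries$n_bases_covered > 0]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
}

#' Conservation filter of the candidate cascade
#'
#' Keeps candidates whose conserved-base fraction is at least
#' `min_conserved_fraction`, preserving input order.
#'
#' @param candidates character vector of transcript ids
#' @param summaries data.frame from [summarize_conservation()]
#' @param min_conserved_fraction threshold in \[0, 1\]
#' @return filtered id vector
#' @export
conservation_filter <- function(candidates, summaries,
                                min_conserved_fraction = 0.1) {
  idx <- match(candidates, summaries$transcript_id)
  if (anyNA(idx))
    stop("no conservation summary for candidate(s): ",
         paste(candidates[is.na(idx)], collapse = ", "))
  frac <- summaries$conserved_fraction[idx]
  frac[is.na(frac)] <- 0
  candidates[frac >= min_conserved_fraction]
}

#' Write conservation summaries as TSV
#' @param summaries data.frame from [summarize_conservation()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_conservation <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
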