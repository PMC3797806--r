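# Independent oracles used to validate the package implementations.
# These deliberately avoid GenomicRanges and the package's own code paths:
# plain arithmetic over data.frames, brute-force enumeration.

# gap between closed intervals (0 when overlapping or adjacent)
oracle_gap <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2) - 1)

oracle_overlaps <- function(s1, e1, s2, e2) min(e1, e2) - max(s1, s2) + 1 > 0

# brute-force positional classifier: enumerates every (lncRNA, gene) pair
# and applies the class definitions in precedence order
oracle_classify_one <- function(l, genes, exons_by, window_bp = 1e5,
                                bidirectional_gap_bp = 1000) {
  res <- list(positional_class = "intergenic",
              neighbor_gene_id = NA_character_, distance_bp = NA_real_)
  g <- genes[genes$chrom == l$chrom, , drop = FALSE]
  if (nrow(g) == 0) return(res)
  same <- g[g$strand == l$strand, , drop = FALSE]
  opp <- g[g$strand != l$strand, , drop = FALSE]
  pick <- function(ids) sort(ids)[1]

  # 1: same strand, exon overlap
  hit <- character(0)
  for (i in seq_len(nrow(same))) {
    ex <- exons_by[[same$transcript_id[i]]]
    if (any(mapply(oracle_overlaps, l$start, l$end, ex$start, ex$end)))
      hit <- c(hit, same$transcript_id[i])
  }
  if (length(hit) > 0)
    return(list(positional_class = "exon_sense_overlapping",
                neighbor_gene_id = pick(hit), distance_bp = 0))
  # 2: same strand, contained in a gene span
  hit <- same$transcript_id[l$start >= same$start & l$end <= same$end]
  if (length(hit) > 0)
    return(list(positional_class = "intron_sense_overlapping",
                neighbor_gene_id = pick(hit), distance_bp = 0))
  # 3/4: opposite strand overlap
  nat <- character(0); ia <- character(0)
  for (i in seq_len(nrow(opp))) {
    if (!oracle_overlaps(l$start, l$end, opp$start[i], opp$end[i])) next
    ex <- exons_by[[opp$transcript_id[i]]]
    exonic <- any(mapply(oracle_overlaps, l$start, l$end, ex$start, ex$end))
    contained <- l$start >= opp$start[i] & l$end <= opp$end[i]
    if (exonic || !contained) nat <- c(nat, opp$transcript_id[i])
    else ia <- c(ia, opp$transcript_id[i])
  }
  if (length(nat) > 0)
    return(list(positional_class = "natural_antisense",
                neighbor_gene_id = pick(nat), distance_bp = 0))
  if (length(ia) > 0)
    return(list(positional_class = "intronic_antisense",
                neighbor_gene_id = pick(ia), distance_bp = 0))
  # 5: bidirectional (opposite strand, disjoint, TSS gap within bound)
  if (nrow(opp) > 0) {
    ltss <- if (l$strand == "+") l$start else l$end
    gtss <- ifelse(opp$strand == "+", opp$start, opp$end)
    disjoint <- !mapply(oracle_overlaps, l$start, l$end, opp$start, opp$end)
    tgap <- abs(ltss - gtss)
    cand <- which(disjoint & tgap <= bidirectional_gap_bp)
    if (length(cand) > 0) {
      o <- cand[order(tgap[cand], opp$transcript_id[cand])][1]
      return(list(positional_class = "bidirectional",
                  neighbor_gene_id = opp$transcript_id[o],
                  distance_bp = oracle_gap(l$start, l$end, opp$start[o],
                                           opp$end[o])))
    }
  }
  # 6: intergenic, nearest gene with gap strictly below the window
  gaps <- mapply(oracle_gap, l$start, l$end, g$start, g$end)
  inwin <- which(gaps < window_bp)
  if (length(inwin) > 0) {
    mn <- inwin[gaps[inwin] == min(gaps[inwin])]
    if (length(mn) > 1) {   # tie: 5' gene on the lncRNA's strand
      fp <- if (l$strand == "+") g$start[mn] else -g$end[mn]
      mn <- mn[order(fp, g$transcript_id[mn])]
    }
    res$neighbor_gene_id <- g$transcript_id[mn[1]]
    res$distance_bp <- gaps[mn[1]]
  }
  res
}

oracle_classify <- function(annotation, window_bp = 1e5,
                            bidirectional_gap_bp = 1000) {
  tx <- annotation$transcripts
  genes <- tx[tx$biotype == "protein_coding", , drop = FALSE]
  lnc <- tx[tx$biotype == "lncRNA", , drop = FALSE]
  exons_by <- split(annotation$exons, annotation$exons$transcript_id)
  do.call(rbind, lapply(seq_len(nrow(lnc)), function(i) {
    r <- oracle_classify_one(lnc[i, ], genes, exons_by, window_bp,
                             bidirectional_gap_bp)
    data.frame(lncrna_id = lnc$transcript_id[i],
               positional_class = r$positional_class,
               neighbor_gene_id = r$neighbor_gene_id,
               distance_bp = r$distance_bp, stringsAsFactors = FALSE)
  }))
}

# random small genome with arbitrary geometry (coding genes non-overlapping,
# lncRNAs placed uniformly, including on top of genes)
random_genome <- function(n_genes = 50, n_lnc = 30, chrom_len = 2e6,
                          n_chrom = 2) {
  gene_rows <- list(); exon_rows <- list()
  for (ch in paste0("c", seq_len(n_chrom))) {
    pos <- 1000
    ng <- ceiling(n_genes / n_chrom)
    for (i in seq_len(ng)) {
      w <- sample(2000:15000, 1)
      start <- pos + sample(500:20000, 1)
      if (start + w > chrom_len) break
      id <- sprintf("G_%s_%03d", ch, i)
      strand <- sample(c("+", "-"), 1)
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        transcript_id = id, chrom = ch, start = start, end = start + w,
        strand = strand, biotype = "protein_coding")
      # 2-3 exons
      ne <- sample(2:3, 1)
      cuts <- sort(sample(seq(start + 100, start + w - 100, by = 50),
                          2 * ne - 2))
      bounds <- c(start, cuts, start + w)
      for (e in seq_len(ne)) {
        exon_rows[[length(exon_rows) + 1]] <- data.frame(
          transcript_id = id, chrom = ch, start = bounds[2 * e - 1],
          end = bounds[2 * e] - (if (e < ne) 1 else 0), strand = strand)
      }
      pos <- start + w
    }
  }
  genes <- do.call(rbind, gene_rows)
  lnc_rows <- list()
  for (i in seq_len(n_lnc)) {
    ch <- sample(unique(genes$chrom), 1)
    w <- sample(200:5000, 1)
    start <- sample(seq_len(chrom_len - w), 1)
    id <- sprintf("L_%03d", i)
    lnc_rows[[length(lnc_rows) + 1]] <- data.frame(
      transcript_id = id, chrom = ch, start = start, end = start + w,
      strand = sample(c("+", "-"), 1), biotype = "lncRNA")
  }
  lnc <- do.call(rbind, lnc_rows)
  lnc_ex <- lnc[c("transcript_id", "chrom", "start", "end", "strand")]
  # fix exon bounds so adjacent exons do not touch
  exons <- do.call(rbind, exon_rows)
  transcript_set(rbind(genes, lnc), rbind(exons, lnc_ex))
}

# exhaustive hypergeometric upper tail: P(X >= k) by direct enumeration
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# base-by-base conservation oracle: expand the track to per-base scores
oracle_conservation <- function(track_df, exons_df) {
  # track_df: chrom, start, end, score (1-based closed)
  pos_score <- list()
  for (i in seq_len(nrow(track_df))) {
    p <- track_df$start[i]:track_df$end[i]
    pos_score[[i]] <- data.frame(chrom = track_df$chrom[i], pos = p,
                                 score = track_df$score[i])
  }
  ps <- do.call(rbind, pos_score)
  scores <- numeric(0)
  for (i in seq_len(nrow(exons_df))) {
    m <- ps$chrom == exons_df$chrom[i] & ps$pos >= exons_df$start[i] &
      ps$pos <= exons_df$end[i]
    scores <- c(scores, ps$score[m])
  }
  if (length(scores) == 0)
    return(list(n = 0, median = NA_real_, frac = NA_real_))
  list(n = length(scores), median = median(scores),
       frac = mean(scores >= 0.5))
}
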