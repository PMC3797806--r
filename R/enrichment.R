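#' Gene-set over-representation of lncRNA neighbor genes
#'
#' The functional interpretation of dysregulated lncRNAs is carried by their
#' closest protein-coding genes. Gene sets (GO terms, pathways) are tested
#' for over-representation among neighbor genes with the one-sided
#' hypergeometric (Fisher) test, a Pearson chi-square alternative, and
#' Benjamini-Hochberg FDR correction. The universe is the neighbor-gene
#' universe (coding genes that are the neighbor of any profiled lncRNA), not
#' the whole genome.
#'
#' @name enrichment
NULL

#' Gene-set collection
#'
#' @param sets named list of character vectors (set id -> member gene ids);
#'   an optional `names` attribute per set id can be carried in
#'   `descriptions`.
#' @param universe character vector of gene ids; set members are restricted
#'   to it and sets empty after restriction are dropped.
#' @param descriptions optional named character vector of set descriptions.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  sets <- sets[lengths(sets) > 0]
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  structure(list(sets = sets, universe = universe,
                 descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets over a universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Read a GMT file into a gene_set_collection
#' @param path GMT file (tab-separated: set id, description, members...)
#' @param universe gene universe to restrict against
#' @return a `gene_set_collection`
#' @export
read_gmt <- function(path, universe) {
  sets <- fgsea::gmtPathways(path)
  # second GMT column (description) is dropped by the reader; re-read it
  desc <- vapply(strsplit(readLines(path), "\t"), function(f) f[2], "")
  names(desc) <- vapply(strsplit(readLines(path), "\t"), function(f) f[1], "")
  gene_set_collection(sets, universe, descriptions = desc)
}

#' Write gene sets as GMT
#' @param sets named list of character vectors
#' @param path output path
#' @param descriptions optional named descriptions (defaults to the set ids)
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Neighbor-gene query sets for enrichment
#'
#' @param classified data.frame from [classify_lncrnas()]
#' @param up_ids,down_ids lncRNA ids from [volcano_filter()]
#' @return list with `up_genes`, `down_genes` (deduplicated neighbor genes of
#'   up-/down-regulated lncRNAs) and `universe_genes` (neighbors of all
#'   profiled lncRNAs).
#' @export
neighbor_gene_sets <- function(classified, up_ids, down_ids) {
  nb <- function(ids) {
    g <- classified$neighbor_gene_id[classified$lncrna_id %in% ids]
    sort(unique(g[!is.na(g)]))
  }
  list(up_genes = nb(up_ids), down_genes = nb(down_ids),
       universe_genes = nb(classified$lncrna_id))
}

hypergeom_fields <- function(query, collection) {
  N <- length(collection$universe)
  query <- intersect(unique(query), collection$universe)
  n <- length(query)
  K <- lengths(collection$sets)
  k <- vapply(collection$sets, function(s) length(intersect(query, s)),
              integer(1))
  data.frame(set_id = names(collection$sets),
             name = unname(collection$descriptions[names(collection$sets)]),
             k = unname(k), n = n, K = unname(K), N = N,
             stringsAsFactors = FALSE)
}

odds_ratio_2x2 <- function(k, n, K, N) {
  a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
  ifelse(b * c == 0, Inf, (a * d) / (b * c))
}

#' One-sided hypergeometric (Fisher) enrichment
#'
#' For each set, p = P(X >= k) where X ~ Hypergeometric(N, K, n): the
#' upper-tail probability of drawing at least the observed overlap. FDR is
#' Benjamini-Hochberg across sets; results are sorted by ascending p.
#'
#' @param query character vector of gene ids (restricted to the universe)
#' @param collection a `gene_set_collection`
#' @return data.frame with `set_id`, `name`, `k`, `n`, `K`, `N`, `p_value`,
#'   `fdr`, `odds_ratio`; empty (with a warning) for an empty query.
#' @export
fisher_enrichment <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  tab <- hypergeom_fields(query, collection)
  if (nrow(tab) == 0 || tab$n[1] == 0) {
    warning("empty query; no enrichment results")
    return(tab[0, ])
  }
  tab$p_value <- stats::phyper(tab$k - 1, tab$K, tab$N - tab$K, tab$n,
                               lower.tail = FALSE)
  tab$fdr <- bh_fdr(tab$p_value)
  tab$odds_ratio <- odds_ratio_2x2(tab$k, tab$n, tab$K, tab$N)
  tab[order(tab$p_value, tab$set_id), ]
}

#' Pearson chi-square enrichment (no continuity correction)
#'
#' The chi-square companion test on the same 2x2 table. Flagged unreliable
#' when any expected cell count is below 5; degenerate margins give p = 1.
#'
#' @inheritParams fisher_enrichment
#' @return data.frame as for [fisher_enrichment()] plus `statistic` and
#'   `unreliable` flag.
#' @export
chi2_enrichment <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  tab <- hypergeom_fields(query, collection)
  if (nrow(tab) == 0 || tab$n[1] == 0) {
    warning("empty query; no enrichment results")
    return(tab[0, ])
  }
  res <- t(vapply(seq_len(nrow(tab)), function(i) {
    a <- tab$k[i]; b <- tab$n[i] - tab$k[i]
    c <- tab$K[i] - tab$k[i]; d <- tab$N[i] - tab$K[i] - tab$n[i] + tab$k[i]
    m <- matrix(c(a, b, c, d), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0))
      return(c(stat = 0, p = 1, unreliable = 1))
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    c(stat = unname(ct$statistic), p = ct$p.value,
      unreliable = as.numeric(any(ct$expected < 5)))
  }, numeric(3)))
  tab$statistic <- res[, "stat"]
  tab$p_value <- res[, "p"]
  tab$fdr <- bh_fdr(tab$p_value)
  tab$odds_ratio <- odds_ratio_2x2(tab$k, tab$n, tab$K, tab$N)
  tab$unreliable <- res[, "unreliable"] > 0
  tab[order(tab$p_value, tab$set_id), ]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to \[0, 1\], returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return numeric vector of adjusted values
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
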