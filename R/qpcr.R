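#' Relative quantification of qPCR Ct tables (2^-ddCt)
#'
#' Ct tables hold triplicate cycle-threshold values per (sample, gene).
#' Replicates are averaged on the Ct scale, normalized to a reference gene
#' (GAPDH in the study design) to give dCt = Ct(target) - Ct(reference), then
#' to a calibrator sample or group: ddCt = dCt - mean calibrator dCt, and
#' rq = 2^-ddCt. Amplification efficiency is fixed at perfect doubling.
#'
#' @name qpcr
NULL

#' Read a Ct table from TSV
#' @param path TSV with columns `sample`, `tissue`, `group`, `gene`,
#'   `replicate`, `ct`.
#' @return validated data.frame
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "tissue", "group", "gene", "replicate", "ct")
  if (!all(need %in% names(ct))) stop("Ct table needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  ct
}

#' 2^-ddCt relative quantification
#'
#' @param ct Ct table data.frame (columns `sample`, `gene`, `ct`, optionally
#'   `group`, `tissue`).
#' @param reference_gene gene used for dCt normalization (must be measured in
#'   every sample).
#' @param calibrator a sample id or a group label; ddCt is computed against
#'   the mean dCt of the calibrator sample(s).
#' @param sd_warn replicate SD (cycles) above which a measurement is flagged.
#' @return data.frame with `sample`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `rq` and `flag_high_sd`, plus `group`/`tissue` when present in the
#'   input. The reference gene itself is not reported.
#' @export
ddct_quantify <- function(ct, reference_gene = "GAPDH", calibrator,
                          sd_warn = 0.5) {
  keys <- interaction(ct$sample, ct$gene, drop = TRUE)
  mean_ct <- tapply(ct$ct, keys, mean)
  sd_ct <- tapply(ct$ct, keys, function(v) if (length(v) > 1) stats::sd(v) else 0)
  first <- ct[!duplicated(keys), , drop = FALSE]
  first$mean_ct <- as.numeric(mean_ct[as.character(interaction(
    first$sample, first$gene, drop = TRUE))])
  first$flag_high_sd <- as.numeric(sd_ct[as.character(interaction(
    first$sample, first$gene, drop = TRUE))]) > sd_warn

  ref <- first[first$gene == reference_gene, , drop = FALSE]
  tgt <- first[first$gene != reference_gene, , drop = FALSE]
  miss <- setdiff(unique(tgt$sample), ref$sample)
  if (length(miss) > 0)
    stop("reference gene '", reference_gene, "' missing for sample(s): ",
         paste(miss, collapse = ", "))
  tgt$delta_ct <- tgt$mean_ct - ref$mean_ct[match(tgt$sample, ref$sample)]

  if (calibrator %in% tgt$sample) {
    cal <- tgt$sample == calibrator
  } else if ("group" %in% names(tgt) && calibrator %in% tgt$group) {
    cal <- tgt$group == calibrator
  } else {
    stop("calibrator '", calibrator, "' matches no sample or group")
  }
  cal_dct <- tapply(tgt$delta_ct[cal], tgt$gene[cal], mean)
  if (!all(unique(tgt$gene) %in% names(cal_dct)))
    stop("calibrator lacks measurements for gene(s): ",
         paste(setdiff(unique(tgt$gene), names(cal_dct)), collapse = ", "))
  tgt$delta_delta_ct <- tgt$delta_ct - as.numeric(cal_dct[tgt$gene])
  tgt$rq <- 2^(-tgt$delta_delta_ct)
  keep <- intersect(c("sample", "tissue", "group", "gene", "delta_ct",
                      "delta_delta_ct", "rq", "flag_high_sd"), names(tgt))
  rownames(tgt) <- NULL
  tgt[keep]
}

#' Tissue-predominance of relative expression over a tissue panel
#'
#' For each gene, the share of each tissue is its rq divided by the summed rq
#' over the panel (the calibrator choice cancels). A gene is
#' heart-predominant when heart attains the (strict) maximum share; with
#' `strict_majority = TRUE` the heart share must additionally exceed 0.5.
#'
#' @param rel data.frame from [ddct_quantify()] with a `tissue` column
#'   (one panel sample per tissue per gene).
#' @param heart_tissue tissue label counted as heart.
#' @param strict_majority require share > 0.5 for predominance.
#' @return data.frame with one row per (gene, tissue): `gene`, `tissue`,
#'   `share`, plus per-gene `predominant_tissue` (NA on ties or when all rq
#'   are zero), `heart_share` and `heart_predominant`.
#' @export
tissue_predominance <- function(rel, heart_tissue = "heart",
                                strict_majority = FALSE) {
  if (!"tissue" %in% names(rel)) stop("rel needs a 'tissue' column")
  out <- do.call(rbind, lapply(split(rel, rel$gene), function(g) {
    if (nrow(g) < 2) stop("need >= 2 tissues per gene (gene ",
                          g$gene[1], ")")
    tot <- sum(g$rq)
    share <- if (tot == 0) rep(NA_real_, nrow(g)) else g$rq / tot
    top <- if (tot == 0) NA_character_ else {
      mx <- max(share)
      winners <- g$tissue[share == mx]
      if (length(winners) > 1) NA_character_ else winners  # tie flagged as NA
    }
    hs <- if (heart_tissue %in% g$tissue) share[g$tissue == heart_tissue][1]
          else NA_real_
    hp <- !is.na(top) && identical(top, heart_tissue) &&
      (!strict_majority || (!is.na(hs) && hs > 0.5))
    data.frame(gene = g$gene, tissue = g$tissue, share = share,
               predominant_tissue = top, heart_share = hs,
               heart_predominant = hp, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cis-regulation concordance between a lncRNA and its neighbor gene
#'
#' A lncRNA/neighbor pair is `no_association` when the neighbor's
#' differential p-value is not significant at `alpha`; otherwise
#' `cis_concordant` when the two log2 fold-changes share a sign, else
#' `discordant`.
#'
#' @param lnc_diff,neighbor_diff one-row differential records (from
#'   [differential_test()]) computed on the same sample set.
#' @param alpha significance level for the neighbor's test.
#' @return one of "cis_concordant", "discordant", "no_association".
#' @export
concordance_check <- function(lnc_diff, neighbor_diff, alpha = 0.05) {
  if (neighbor_diff$p_value >= alpha) return("no_association")
  if (sign(lnc_diff$log2fc) == sign(neighbor_diff$log2fc)) "cis_concordant"
  else "discordant"
}
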