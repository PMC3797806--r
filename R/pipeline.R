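#' Candidate-prioritization cascade
#'
#' The five-stage filter that reduces the profiled lncRNAs to validated
#' candidates: (1) volcano filter (fold-change and p-value), (2) functional
#' filter (neighbor gene annotated to a selected heart-development /
#' proliferation / apoptosis / differentiation term), (3) conservation
#' filter (conserved-base fraction), (4) tissue predominance (heart attains
#' the maximum panel share in the qPCR table), (5) cis-regulation check
#' against the neighbor gene's differential record. Stage 4 runs only for
#' lncRNAs present in the Ct table; absent ones are recorded untested and do
#' not advance. Stage 5 is a characterization, not an elimination: reaching
#' it means surviving stages 1-4 with a testable neighbor, and its outcome
#' (`cis_concordant`, `discordant`, `no_association`) is reported rather
#' than filtered on.
#'
#' @name pipeline
NULL

#' Functional filter on neighbor-gene set membership
#'
#' Keeps dysregulated lncRNAs whose neighbor gene belongs to at least one of
#' the listed functional terms. Membership, not enrichment significance, is
#' the criterion; term enrichment is reported separately. Output is ordered
#' by |log2fc| descending (id ascending on ties) when records are supplied,
#' otherwise by id.
#'
#' @param classified data.frame from [classify_lncrnas()]
#' @param up_ids,down_ids volcano-filtered lncRNA ids
#' @param terms character vector of set ids (must exist in `collection`)
#' @param collection a `gene_set_collection`
#' @param records optional differential records for the |log2fc| ordering
#' @return character vector of retained lncRNA ids
#' @export
functional_filter <- function(classified, up_ids, down_ids, terms, collection,
                              records = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(terms) == 0) stop("functional term list is empty")
  missing <- setdiff(terms, names(collection$sets))
  if (length(missing) > 0)
    stop("term(s) absent from collection: ", paste(missing, collapse = ", "))
  term_genes <- unique(unlist(collection$sets[terms]))
  ids <- c(up_ids, down_ids)
  nb <- classified$neighbor_gene_id[match(ids, classified$lncrna_id)]
  keep <- ids[!is.na(nb) & nb %in% term_genes]
  if (!is.null(records)) {
    lfc <- abs(records$log2fc[match(keep, records$probe_id)])
    keep <- keep[order(-lfc, keep)]
  } else keep <- sort(keep)
  keep
}

#' Pipeline configuration
#'
#' @param paths named list of input files: `matrix`, `design`, `annotation`,
#'   `track`, `elements` (optional), `gene_sets`, `ct`.
#' @param fc_threshold,p_threshold volcano thresholds.
#' @param window_bp,bidirectional_gap_bp classification parameters.
#' @param min_conserved_fraction conservation filter threshold.
#' @param alpha significance level of the cis-check.
#' @param functional_terms set ids used by the functional filter.
#' @param track_format conservation track format.
#' @param reference_gene,heart_tissue qPCR parameters.
#' @param matrix_scale "linear" or "log2".
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(paths,
                            fc_threshold = 2.0, p_threshold = 0.05,
                            window_bp = 100000L, bidirectional_gap_bp = 1000L,
                            min_conserved_fraction = 0.1, alpha = 0.05,
                            functional_terms = "CARDIAC_DEV",
                            track_format = "bedGraph",
                            reference_gene = "GAPDH",
                            heart_tissue = "heart",
                            matrix_scale = "linear") {
  need <- c("matrix", "design", "annotation", "track", "gene_sets", "ct")
  if (!all(need %in% names(paths)))
    stop("paths must name: ", paste(need, collapse = ", "))
  if (any(c(fc_threshold, p_threshold, window_bp, bidirectional_gap_bp,
            alpha) <= 0) || min_conserved_fraction < 0)
    stop("thresholds must be positive")
  structure(list(paths = paths, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, window_bp = window_bp,
                 bidirectional_gap_bp = bidirectional_gap_bp,
                 min_conserved_fraction = min_conserved_fraction,
                 alpha = alpha, functional_terms = functional_terms,
                 track_format = track_format, reference_gene = reference_gene,
                 heart_tissue = heart_tissue, matrix_scale = matrix_scale),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with a `paths` block and optional threshold fields
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the candidate-prioritization cascade
#'
#' @param config a `pipeline_config` (or path to its YAML form)
#' @param outdir optional directory for `candidates.tsv`, per-stage TSVs and
#'   `report.json`.
#' @return list with `candidates` (one row per profiled lncRNA:
#'   `lncrna_id`, `direction`, `fold_change`, `positional_class`,
#'   `neighbor_gene_id`, `passed_functional`, `passed_conservation`,
#'   `heart_predominant`, `cis_status`, `stage_reached`), `report` (stage
#'   survivor counts and thresholds) and intermediate tables.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (nm in names(config$paths)) {
    if (!file.exists(config$paths[[nm]]))
      stop("pipeline stage input missing: ", nm, " (", config$paths[[nm]], ")")
  }

  expr <- read_expression(config$paths$matrix, config$paths$design,
                          scale = config$matrix_scale)
  annotation <- read_annotation_gtf(config$paths$annotation)
  lnc_ids <- annotation$transcripts$transcript_id[
    annotation$transcripts$biotype == "lncRNA"]

  norm <- quantile_normalize(expr$matrix)
  records <- differential_test(norm, expr$group)
  lnc_records <- records[records$probe_id %in% lnc_ids, ]
  volcano <- volcano_filter(lnc_records, config$fc_threshold, config$p_threshold)
  dysregulated <- c(volcano$up, volcano$down)

  classified <- classify_lncrnas(annotation,
                                 window_bp = config$window_bp,
                                 bidirectional_gap_bp = config$bidirectional_gap_bp)

  collection <- read_gmt(config$paths$gene_sets,
                         universe = neighbor_gene_sets(
                           classified, volcano$up, volcano$down)$universe_genes)
  s2 <- functional_filter(classified, volcano$up, volcano$down,
                          config$functional_terms, collection,
                          records = lnc_records)

  track <- read_track(config$paths$track,
                      format = if (config$track_format == "bedGraph")
                        "bedGraph" else "fixedStep_wig")
  elements <- if (!is.null(config$paths$elements) &&
                  file.exists(config$paths$elements))
    read_elements_bed(config$paths$elements) else NULL
  summaries <- summarize_conservation(annotation, track, elements,
                                      ids = if (length(dysregulated) > 0)
                                        dysregulated else lnc_ids)
  s3 <- if (length(s2) > 0)
    conservation_filter(s2, summaries, config$min_conserved_fraction)
  else character(0)

  ct <- read_ct_table(config$paths$ct)
  pred <- if (any(ct$group == "panel")) {
    panel <- ct[ct$group == "panel", ]
    rel <- ddct_quantify(panel, reference_gene = config$reference_gene,
                         calibrator = sort(unique(panel$sample))[1])
    tissue_predominance(rel, heart_tissue = config$heart_tissue)
  } else NULL
  heart_pred <- function(id) {
    if (is.null(pred) || !(id %in% pred$gene)) return(NA)
    pred$heart_predominant[pred$gene == id][1]
  }
  s4 <- s3[vapply(s3, function(id) isTRUE(heart_pred(id)), logical(1))]

  cis_for <- function(id) {
    nb <- classified$neighbor_gene_id[classified$lncrna_id == id]
    if (is.na(nb) || !(nb %in% records$probe_id)) return(NA_character_)
    concordance_check(records[records$probe_id == id, ],
                      records[records$probe_id == nb, ], alpha = config$alpha)
  }
  cis <- stats::setNames(vapply(s4, cis_for, character(1)), s4)
  s5 <- s4[!is.na(cis)]

  candidates <- data.frame(
    lncrna_id = lnc_ids,
    direction = ifelse(lnc_ids %in% volcano$up, "up",
                       ifelse(lnc_ids %in% volcano$down, "down", "none")),
    fold_change = records$fold_change[match(lnc_ids, records$probe_id)],
    positional_class = classified$positional_class[
      match(lnc_ids, classified$lncrna_id)],
    neighbor_gene_id = classified$neighbor_gene_id[
      match(lnc_ids, classified$lncrna_id)],
    stringsAsFactors = FALSE)
  candidates$passed_functional <- ifelse(
    candidates$lncrna_id %in% dysregulated,
    candidates$lncrna_id %in% s2, NA)
  candidates$passed_conservation <- ifelse(
    candidates$lncrna_id %in% s2, candidates$lncrna_id %in% s3, NA)
  candidates$heart_predominant <- vapply(candidates$lncrna_id, function(id) {
    if (!(id %in% s3)) NA else heart_pred(id)
  }, logical(1))
  candidates$cis_status <- ifelse(
    candidates$lncrna_id %in% s5, cis[candidates$lncrna_id], "untested")
  candidates$stage_reached <-
    (candidates$lncrna_id %in% dysregulated) +
    (candidates$lncrna_id %in% s2) +
    (candidates$lncrna_id %in% s3) +
    (candidates$lncrna_id %in% s4) +
    (candidates$lncrna_id %in% s5)
  candidates <- candidates[order(-candidates$stage_reached,
                                 -abs(log2(candidates$fold_change)),
                                 candidates$lncrna_id), ]
  rownames(candidates) <- NULL

  report <- list(
    n_profiled_lncrna = length(lnc_ids),
    survivors = list(stage1_volcano = length(dysregulated),
                     stage2_functional = length(s2),
                     stage3_conservation = length(s3),
                     stage4_tissue = length(s4),
                     stage5_cis = length(s5)),
    thresholds = config[setdiff(names(config), "paths")])

  result <- list(candidates = candidates, report = report,
                 differential = records, volcano = volcano,
                 classified = classified, conservation = summaries,
                 predominance = pred, cis = cis)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(candidates, file.path(outdir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_differential(records, file.path(outdir, "stage1_differential.tsv"))
    write_classification(classified, file.path(outdir, "stage2_classification.tsv"))
    write_conservation(summaries, file.path(outdir, "stage3_conservation.tsv"))
    if (!is.null(pred))
      utils::write.table(pred, file.path(outdir, "stage4_predominance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
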