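#' Expression matrix handling, differential testing and volcano filtering
#'
#' The array design is two conditions (VSD vs NC). Matrices are probes x
#' samples; scanner output is linear-scale intensity and is log2-transformed
#' (with pseudocount 1) at load.
#'
#' @name expression
NULL

#' Read an expression matrix and its design from TSV
#'
#' @param matrix_path TSV with a `probe_id` column followed by one column per
#'   sample.
#' @param design_path TSV with columns `sample` and `group` (values "VSD" or
#'   "NC").
#' @param scale "linear" (default; log2(x + 1) is applied) or "log2".
#' @return list with `matrix` (numeric, log2 scale, rownames = probe ids) and
#'   `group` (named character vector over samples).
#' @export
read_expression <- function(matrix_path, design_path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(matrix_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (anyNA(m)) stop("expression matrix contains missing values; ",
                     "impute or filter before loading")
  if (scale == "linear") m <- log2(m + 1)
  design <- utils::read.delim(design_path)
  if (!all(colnames(m) %in% design$sample))
    stop("design is missing samples present in the matrix")
  group <- stats::setNames(as.character(design$group), design$sample)[colnames(m)]
  list(matrix = m, group = group)
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the identical distribution: the
#' value at rank r in each column is replaced by the mean of the rank-r
#' values across columns. Ties are broken by original order, which makes the
#' transform idempotent.
#'
#' @param m numeric matrix, probes x samples, no missing values.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("matrix must be numeric")
  if (anyNA(m)) stop("missing values present; impute or filter first")
  if (ncol(m) < 1 || nrow(m) == 0) stop("empty matrix")
  ord <- apply(m, 2, order)
  sorted <- apply(m, 2, sort)
  if (nrow(m) == 1) { ord <- matrix(ord, nrow = 1); sorted <- matrix(sorted, nrow = 1) }
  mu <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) out[ord[, j], j] <- mu
  out
}

#' Two-group differential expression per probe
#'
#' Welch's unpaired two-sample t-test by default (two biological conditions
#' with no defined pairing); a paired t-test is available when samples are
#' matched by order within groups. Within-group variances are floored at
#' `var_floor` so noiseless fixtures yield finite statistics instead of NaN.
#'
#' @param m log2-scale matrix, probes x samples.
#' @param group named character vector mapping sample to "VSD"/"NC" (names
#'   must cover `colnames(m)`).
#' @param paired use a paired t-test (requires equal group sizes; pairs are
#'   matched by within-group column order).
#' @param var_floor lower bound on within-group variance (log2 scale).
#' @return data.frame with `probe_id`, `log2fc` (VSD mean - NC mean),
#'   `fold_change` (= 2^|log2fc|, >= 1), `p_value`, `direction` ("up"/"down"),
#'   `var_floored` flag.
#' @export
differential_test <- function(m, group, paired = FALSE, var_floor = 1e-8) {
  m <- as.matrix(m)
  group <- group[colnames(m)]
  if (anyNA(group)) stop("every sample needs a group label")
  a <- m[, group == "VSD", drop = FALSE]
  b <- m[, group == "NC", drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group for the t-test")
  mean1 <- rowMeans(a); mean2 <- rowMeans(b)
  lfc <- mean1 - mean2
  if (paired) {
    if (n1 != n2) stop("paired test requires equal group sizes")
    d <- a - b
    vd <- pmax(apply(d, 1, stats::var), var_floor)
    floored <- apply(d, 1, stats::var) < var_floor
    tstat <- rowMeans(d) / sqrt(vd / n1)
    df <- n1 - 1
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    v1r <- apply(a, 1, stats::var); v2r <- apply(b, 1, stats::var)
    floored <- v1r < var_floor | v2r < var_floor
    v1 <- pmax(v1r, var_floor); v2 <- pmax(v2r, var_floor)
    se2 <- v1 / n1 + v2 / n2
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  data.frame(probe_id = rownames(m),
             log2fc = lfc,
             fold_change = 2^abs(lfc),
             p_value = p,
             direction = ifelse(lfc > 0, "up", "down"),
             var_floored = floored,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Volcano filter
#'
#' Retains probes with `fold_change > fc_threshold` and
#' `p_value < p_threshold` (both strict), split by direction.
#'
#' @param records data.frame from [differential_test()]
#' @param fc_threshold fold-change threshold (linear scale), default 2.
#' @param p_threshold p-value threshold, default 0.05.
#' @return list with `up` and `down` character vectors of probe ids
#'   (disjoint).
#' @export
volcano_filter <- function(records, fc_threshold = 2.0, p_threshold = 0.05) {
  if (fc_threshold <= 0 || p_threshold <= 0) stop("thresholds must be > 0")
  pass <- records$fold_change > fc_threshold & records$p_value < p_threshold
  list(up = records$probe_id[pass & records$direction == "up"],
       down = records$probe_id[pass & records$direction == "down"])
}

#' Average-linkage sample dendrogram on correlation distance
#'
#' Clusters samples with distance 1 - Pearson correlation and average
#' linkage, the standard display of between-array agreement.
#'
#' @param m normalized log2 matrix, probes x samples.
#' @return an object of class `hclust` over samples.
#' @export
sample_dendrogram <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant expression vector; correlation undefined for sample(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(m))
  stats::hclust(d, method = "average")
}

#' Write differential records as TSV
#' @param records data.frame from [differential_test()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_differential <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
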