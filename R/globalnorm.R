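#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes (those
#' with positive counts in every sample) of the ratio of the gene's
#' count to its geometric mean across samples. Normalized counts are
#' counts divided by the factor.
#'
#' @param counts genes x samples matrix of nonnegative counts (clamped
#'   totals `R0` in this pipeline).
#' @return positive numeric vector of per-sample size factors.
#' @export
median_of_ratios_factors <- function(counts) {
  counts <- .check_count_matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has positive counts in every sample; ",
         "use TMM factors or add pseudocounts")
  log_geo <- rowMeans(log(counts[pos, , drop = FALSE]))
  apply(counts[pos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_geo)))
}

#' TMM size factors (trimmed mean of M-values)
#'
#' Computes edgeR's TMM normalization factors and converts them to
#' effective size factors (normalization factor times library size),
#' rescaled to geometric mean 1, so that they are used exactly like
#' [median_of_ratios_factors()]: normalized counts = counts / factor.
#'
#' @param counts genes x samples matrix of nonnegative counts.
#' @param ref_sample optional reference column (index or name); by
#'   default edgeR picks the sample whose upper quartile is closest to
#'   the mean upper quartile.
#' @param trim_M two-sided trim fraction on log-ratios (M-values).
#' @param trim_A two-sided trim fraction on average log-abundances.
#' @return positive numeric vector of per-sample size factors with
#'   geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_M = 0.30, trim_A = 0.05) {
  counts <- .check_count_matrix(counts)
  if (!any(rowSums(counts > 0) == ncol(counts)))
    stop("no gene has positive counts in every sample; ",
         "TMM has no usable genes — add pseudocounts")
  ref <- if (is.null(ref_sample)) NULL else
    if (is.character(ref_sample)) match(ref_sample, colnames(counts)) else ref_sample
  nf <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                               logratioTrim = trim_M, sumTrim = trim_A)
  sf <- nf * colSums(counts)
  sf / exp(mean(log(sf)))
}

#' Normalize a count matrix by size factors
#'
#' @param counts genes x samples matrix.
#' @param factors per-sample size factors.
#' @return matrix of `counts[, j] / factors[j]`.
#' @export
normalize_counts <- function(counts, factors) {
  counts <- .check_count_matrix(counts)
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  sweep(counts, 2, factors, "/")
}

#' Remove genes weakly expressed in both conditions
#'
#' A gene is retained iff its mean count reaches `min_mean` in at least
#' one of the two conditions; genes with mean below the threshold in
#' both are dropped. The threshold is phrased on the (raw-scale,
#' normalized) count means, default 5 reads.
#'
#' @param counts genes x samples matrix.
#' @param condition factor/character of length `ncol(counts)` with two
#'   levels assigning each sample to a condition.
#' @param min_mean retention threshold on the per-condition mean count.
#' @return the filtered matrix (possibly zero rows).
#' @export
filter_low_expression <- function(counts, condition, min_mean = 5) {
  counts <- .check_count_matrix(counts)
  condition <- as.factor(condition)
  stopifnot(length(condition) == ncol(counts), nlevels(condition) == 2L)
  means <- vapply(levels(condition), function(l)
    rowMeans(counts[, condition == l, drop = FALSE]), numeric(nrow(counts)))
  means <- matrix(means, nrow = nrow(counts))
  counts[means[, 1] >= min_mean | means[, 2] >= min_mean, , drop = FALSE]
}

.check_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("count matrix has negative entries")
  counts
}

#' Assemble a count matrix from per-sample local-normalization results
#'
#' @param norm_by_sample named list (one element per sample) of lists of
#'   `local_norm` objects as returned by [local_normalize_all()].
#' @param use_clamped take the clamped totals `R0` (default) or the raw
#'   totals `R`.
#' @return genes x samples numeric matrix.
#' @export
count_matrix_from_localnorm <- function(norm_by_sample, use_clamped = TRUE) {
  stopifnot(length(norm_by_sample) >= 2L)
  genes <- names(norm_by_sample[[1L]])
  field <- if (use_clamped) "R0" else "R"
  mat <- vapply(norm_by_sample, function(res) {
    stopifnot(identical(names(res), genes))
    vapply(res[genes], `[[`, numeric(1), field)
  }, numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, names(norm_by_sample)))
  mat
}
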