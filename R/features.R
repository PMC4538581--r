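#' Bounded fold-change attribute
#'
#' `FC = 1 / (1 + |log2((M1 + pc) / (M2 + pc))|)`, where `M1`, `M2` are
#' the mean normalized counts of the gene in the two conditions and `pc`
#' a pseudocount guarding zeros. Equal means give 1; every doubling of
#' the ratio roughly halves the attribute; the range is (0, 1] and the
#' attribute is symmetric in its arguments.
#'
#' @param M1,M2 nonnegative mean counts.
#' @param pseudocount added to both means inside the log ratio.
#' @return FC in (0, 1].
#' @export
fold_change_attribute <- function(M1, M2, pseudocount = 1) {
  stopifnot(all(M1 >= 0), all(M2 >= 0))
  1 / (1 + abs(log2((M1 + pseudocount) / (M2 + pseudocount))))
}

#' Bounded length-normalized abundance attribute (ARPK)
#'
#' Averaged reads per kilobase mapped into (0, 1]:
#' `ARPK = 1 / (1 + max(0, log2(1000 * (M1 + M2) / (2 * TL))))`.
#' The log term is floored at zero so low-abundance genes (fewer than
#' one read per kilobase) saturate at 1 rather than escaping the unit
#' interval; `mode = "abs"` uses the absolute value instead.
#'
#' @param M1,M2 mean normalized counts per condition.
#' @param TL transcript length in bases (> 0).
#' @param mode `"clamp"` (floor the log at 0, default) or `"abs"`.
#' @return ARPK in (0, 1].
#' @export
arpk_attribute <- function(M1, M2, TL, mode = c("clamp", "abs")) {
  mode <- match.arg(mode)
  stopifnot(all(TL > 0))
  arg <- 1000 * (M1 + M2) / (2 * TL)
  lg <- ifelse(arg > 0, log2(arg), -Inf)  # M1=M2=0 -> floored below
  lg <- if (mode == "clamp") pmax(0, lg) else abs(lg)
  1 / (1 + lg)
}

#' Relative GC-content attribute
#'
#' `GCC = 1 / (1 + c / C)` where `c` is the mean GC fraction of the
#' reads mapped to the gene (both conditions pooled, raw reads) and `C`
#' the mean GC fraction over all mapped reads. A gene matching the
#' global composition scores 0.5; GC-rich genes score lower.
#'
#' @param c_gene per-gene mean read GC fraction (>= 0).
#' @param C_global global mean read GC fraction (> 0).
#' @return GCC in (0, 1].
#' @export
gcc_attribute <- function(c_gene, C_global) {
  if (any(C_global <= 0)) stop("global mean GC fraction must be positive (no mapped reads?)")
  stopifnot(all(c_gene >= 0))
  1 / (1 + c_gene / C_global)
}

#' Three-way label from a reference absolute log2 fold change
#'
#' Genes with `|log2 FC| > hi` are differentially expressed (`DE`),
#' below `lo` not differentially expressed (`NDE`), and in between
#' `NOCALL`.
#'
#' @param abs_log2fc nonnegative absolute log2 fold change(s).
#' @param hi,lo thresholds (defaults 1.5 and 0.5).
#' @return character vector over `{"DE", "NOCALL", "NDE"}`.
#' @export
label_from_log2fc <- function(abs_log2fc, hi = 1.5, lo = 0.5) {
  stopifnot(lo >= 0, lo <= hi, all(abs_log2fc >= 0))
  ifelse(abs_log2fc > hi, "DE", ifelse(abs_log2fc < lo, "NDE", "NOCALL"))
}

#' Build the per-gene feature table
#'
#' Combines a filtered, normalized count matrix with gene lengths and GC
#' statistics into one row per gene carrying the three classifier
#' attributes. `M1`/`M2` are means across the replicates of each
#' condition (with a single replicate, the single values); `c` is the
#' gene's mean read GC fraction pooled over both conditions from the raw
#' assigned reads, and `C` the global mean. Genes without GC information
#' fall back to `c = C` (neutral GCC of 0.5).
#'
#' @param counts_norm filtered, normalized genes x samples matrix.
#' @param condition two-level factor over the columns; the first level
#'   is condition 1 (numerator of `M1`).
#' @param models named list of `gene_model` objects (for `TL`).
#' @param gc_stats optional pooled GC statistics: list with `gene_mean`
#'   (named per-gene mean read GC) and `global_mean`; see
#'   [pool_gc_stats()]. `NULL` sets every gene's `c = C = 0.5`.
#' @param pseudocount passed to [fold_change_attribute()].
#' @param arpk_mode passed to [arpk_attribute()].
#' @return data.frame `gene_id, M1, M2, TL, c, C, FC, ARPK, GCC`.
#' @export
build_feature_table <- function(counts_norm, condition, models, gc_stats = NULL,
                                pseudocount = 1, arpk_mode = "clamp") {
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2L, length(condition) == ncol(counts_norm))
  genes <- rownames(counts_norm)
  known <- genes %in% names(models)
  if (any(!known)) {
    warning(sum(!known), " gene(s) missing from the annotation; skipped")
    counts_norm <- counts_norm[known, , drop = FALSE]
    genes <- genes[known]
  }
  lev <- levels(condition)
  M1 <- rowMeans(counts_norm[, condition == lev[1L], drop = FALSE])
  M2 <- rowMeans(counts_norm[, condition == lev[2L], drop = FALSE])
  TL <- vapply(models[genes], `[[`, integer(1), "TL")
  if (is.null(gc_stats)) {
    C <- 0.5
    c_gene <- rep(C, length(genes))
  } else {
    C <- gc_stats$global_mean
    c_gene <- gc_stats$gene_mean[genes]
    c_gene[is.na(c_gene)] <- C
  }
  data.frame(
    gene_id = genes,
    M1 = unname(M1), M2 = unname(M2), TL = unname(TL),
    c = unname(c_gene), C = C,
    FC = unname(fold_change_attribute(M1, M2, pseudocount)),
    ARPK = unname(arpk_attribute(M1, M2, TL, arpk_mode)),
    GCC = unname(gcc_attribute(c_gene, C)),
    row.names = NULL
  )
}

#' Pool per-sample GC statistics across samples
#'
#' Per-gene and global mean read GC fractions pooled over the raw
#' assigned reads of all samples (both conditions), as used by the GCC
#' attribute.
#'
#' @param depth_sets list of `depth_set` objects with `gc` components.
#' @return list with `gene_mean` (named numeric) and `global_mean`.
#' @export
pool_gc_stats <- function(depth_sets) {
  stopifnot(length(depth_sets) >= 1L)
  genes <- names(depth_sets[[1L]]$gc$gene_sum)
  gsum <- Reduce(`+`, lapply(depth_sets, function(d) d$gc$gene_sum[genes]))
  gn <- Reduce(`+`, lapply(depth_sets, function(d) d$gc$gene_n[genes]))
  total_sum <- sum(vapply(depth_sets, function(d) d$gc$global_sum, numeric(1)))
  total_n <- sum(vapply(depth_sets, function(d) d$gc$global_n, numeric(1)))
  if (total_n == 0L) stop("no reads with GC information")
  list(gene_mean = ifelse(gn > 0, gsum / gn, NA_real_),
       global_mean = total_sum / total_n)
}
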