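#' Run the full differential-expression pipeline
#'
#' Executes the stages in order: parse annotation, build per-sample
#' read-start depth vectors and GC statistics from SAM, clamp each
#' gene's depths to Poisson confidence limits (local normalization),
#' assemble the clamped totals into a count matrix, scale between
#' samples (median-of-ratios or TMM), drop genes weakly expressed in
#' both conditions, compute the three bounded attributes, train a
#' Gaussian naive Bayes model on the supplied labeled table and score
#' every surviving gene. The pipeline is fully deterministic: reruns on
#' identical inputs give identical outputs.
#'
#' @param sam_files named list with two elements (the conditions), each
#'   a character vector of SAM paths (>= 1 replicate per condition).
#' @param annotation path to the GTF/GFF3 annotation.
#' @param training_table labeled feature table with columns
#'   `label, FC, ARPK, GCC` (label in `{"DE","NDE"}`; `NOCALL` rows are
#'   dropped from training).
#' @param upper_p,lower_p local-normalization clamp levels.
#' @param local_norm set `FALSE` to bypass the clamp (raw totals `R`
#'   used downstream), for with/without comparisons.
#' @param global_norm `"deseq"` (median-of-ratios, default) or `"tmm"`.
#' @param min_mean low-expression filter threshold.
#' @param pseudocount,arpk_mode feature-extraction options.
#' @param attributes classifier attribute subset.
#' @param out_dir if given, every stage's table is written there as TSV
#'   (depths, local-norm summaries, size factors, counts, features,
#'   scores) so stages can be inspected and re-entered.
#' @return list with `scores` (ranked data.frame `gene_id, score,
#'   rank`), `features`, `counts_norm`, `size_factors`, `localnorm`
#'   (per-sample summary tables), `model`, and `report` (read-assignment
#'   tallies and discarded-read summary per sample).
#' @export
run_pipeline <- function(sam_files, annotation, training_table,
                         upper_p = 0.975, lower_p = 0.025,
                         local_norm = TRUE,
                         global_norm = c("deseq", "tmm"),
                         min_mean = 5, pseudocount = 1,
                         arpk_mode = "clamp",
                         attributes = c("FC", "ARPK", "GCC"),
                         out_dir = NULL) {
  global_norm <- match.arg(global_norm)
  stopifnot(is.list(sam_files), length(sam_files) == 2L,
            all(lengths(sam_files) >= 1L))
  if (is.null(names(sam_files))) names(sam_files) <- c("cond1", "cond2")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  models <- stage("annotation", parse_annotation(annotation))

  condition <- rep(names(sam_files), lengths(sam_files))
  paths <- unlist(sam_files, use.names = FALSE)
  sample_ids <- paste0(condition, "_r",
                       unlist(lapply(lengths(sam_files), seq_len)))
  depth_sets <- stage("readcount", {
    out <- vector("list", length(paths))
    for (i in seq_along(paths))
      out[[i]] <- build_depth_vectors(paths[i], models, sample_ids[i])
    stats::setNames(out, sample_ids)
  })

  ln <- stage("localnorm",
    lapply(depth_sets, local_normalize_all, upper_p = upper_p, lower_p = lower_p))
  counts <- count_matrix_from_localnorm(ln, use_clamped = local_norm)

  factors <- stage("globalnorm",
    if (global_norm == "deseq") median_of_ratios_factors(counts)
    else tmm_factors(counts))
  counts_norm <- normalize_counts(counts, factors)
  counts_kept <- filter_low_expression(counts_norm, condition, min_mean)

  gc_stats <- stage("gc", pool_gc_stats(depth_sets))
  features <- stage("features",
    build_feature_table(counts_kept, condition, models, gc_stats,
                        pseudocount = pseudocount, arpk_mode = arpk_mode))

  train <- training_table[training_table$label %in% c("DE", "NDE"), , drop = FALSE]
  model <- stage("classifier", nb_train(train, attributes))
  scores <- stage("scoring", nb_score(model, features))
  ranked <- rank_gene_scores(features$gene_id, scores)

  report <- list(
    samples = data.frame(sample_id = sample_ids, condition = condition,
                         path = paths,
                         size_factor = unname(factors)),
    assignment = do.call(rbind, lapply(depth_sets, function(d)
      as.data.frame(as.list(d$log)))),
    localnorm_summary = do.call(rbind, lapply(names(ln), function(s) {
      tab <- local_norm_table(ln[[s]], s)
      data.frame(sample_id = s,
                 total_R = sum(tab$R), total_R0 = sum(tab$R0),
                 total_discarded = sum(tab$discarded),
                 total_added = sum(tab$added),
                 genes_over_10pct = sum(tab$discarded_fraction > 0.10))
    })),
    n_genes_annotated = length(models),
    n_genes_after_filter = nrow(counts_kept),
    local_norm = local_norm, global_norm = global_norm
  )
  res <- list(scores = ranked, features = features,
              counts_norm = counts_kept, size_factors = factors,
              localnorm = lapply(names(ln), function(s) local_norm_table(ln[[s]], s)),
              model = model, report = report)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, depth_sets, out_dir)
  res
}

.write_pipeline_outputs <- function(res, depth_sets, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (d in depth_sets)
    write_depth_tsv(d, file.path(out_dir, paste0("depth_", d$sample_id, ".tsv")))
  for (tab in res$localnorm)
    wt(tab, paste0("localnorm_", tab$sample_id[1L], ".tsv"))
  wt(data.frame(sample_id = names(res$size_factors),
                size_factor = unname(res$size_factors)), "size_factors.tsv")
  wt(data.frame(gene_id = rownames(res$counts_norm), res$counts_norm,
                check.names = FALSE), "counts_normalized.tsv")
  wt(res$features, "features.tsv")
  wt(res$scores, "scores.tsv")
  nb_model_write_json(res$model, file.path(out_dir, "nb_model.json"))
  invisible(out_dir)
}

#' Per-gene log2 fold changes with and without local normalization
#'
#' Runs the counting, clamping and global-scaling stages twice —
#' identical except for the local-normalization switch — and reports
#' each gene's raw-scale log2 ratio side by side. Genes whose depth
#' contains a non-random peak in one condition show a large
#' `log2FC_without` that shrinks substantially once the peak is
#' clamped.
#'
#' @inheritParams run_pipeline
#' @param genes optional gene ids to restrict the report to.
#' @return data.frame `gene_id, log2FC_without, log2FC_with`.
#' @export
report_with_without_localnorm <- function(sam_files, annotation,
                                          upper_p = 0.975, lower_p = 0.025,
                                          global_norm = c("deseq", "tmm"),
                                          pseudocount = 1,
                                          genes = NULL) {
  global_norm <- match.arg(global_norm)
  if (is.null(names(sam_files))) names(sam_files) <- c("cond1", "cond2")
  models <- parse_annotation(annotation)
  condition <- rep(names(sam_files), lengths(sam_files))
  paths <- unlist(sam_files, use.names = FALSE)
  sample_ids <- paste0(condition, "_r",
                       unlist(lapply(lengths(sam_files), seq_len)))
  depth_sets <- stats::setNames(lapply(seq_along(paths), function(i)
    build_depth_vectors(paths[i], models, sample_ids[i])), sample_ids)
  ln <- lapply(depth_sets, local_normalize_all, upper_p = upper_p, lower_p = lower_p)
  lfc_for <- function(use_clamped) {
    counts <- count_matrix_from_localnorm(ln, use_clamped = use_clamped)
    factors <- if (global_norm == "deseq") median_of_ratios_factors(counts)
               else tmm_factors(counts)
    cn <- normalize_counts(counts, factors)
    M1 <- rowMeans(cn[, condition == names(sam_files)[1L], drop = FALSE])
    M2 <- rowMeans(cn[, condition == names(sam_files)[2L], drop = FALSE])
    log2((M1 + pseudocount) / (M2 + pseudocount))
  }
  out <- data.frame(gene_id = names(models),
                    log2FC_without = unname(lfc_for(FALSE)),
                    log2FC_with = unname(lfc_for(TRUE)),
                    row.names = NULL)
  if (!is.null(genes)) out <- out[out$gene_id %in% genes, , drop = FALSE]
  out
}
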