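#' Train a Gaussian naive Bayes model on labeled gene features
#'
#' Estimates class priors as class frequencies and, per class and
#' attribute, the maximum-likelihood mean and variance of a univariate
#' Gaussian (variance with the n-1 denominator, floored at `var_floor`
#' so degenerate columns cannot produce infinite densities). The
#' conditional-independence assumption makes the class-conditional
#' density the product of the per-attribute Gaussians.
#'
#' @param table data.frame with a `label` column over `{"DE","NDE"}` and
#'   one numeric column per attribute.
#' @param attributes attribute subset to train on (default all three).
#' @param var_floor lower bound on the per-attribute variances.
#' @return object of class `nb_model`: list with `classes`, `priors`,
#'   `mean` and `var` (class x attribute matrices), `attributes`,
#'   `var_floor`, `n`.
#' @export
nb_train <- function(table, attributes = c("FC", "ARPK", "GCC"),
                     var_floor = 1e-9) {
  stopifnot(length(attributes) >= 1L, all(attributes %in% names(table)),
            "label" %in% names(table), var_floor > 0)
  classes <- c("DE", "NDE")
  if (!all(classes %in% table$label))
    stop("training table must contain both DE and NDE examples")
  n_by_class <- table(factor(table$label, levels = classes))
  if (any(n_by_class < 2L)) stop("need at least 2 examples per class")
  mu <- sig2 <- matrix(NA_real_, 2L, length(attributes),
                       dimnames = list(classes, attributes))
  floored <- character(0)
  for (cl in classes) {
    x <- as.matrix(table[table$label == cl, attributes, drop = FALSE])
    mu[cl, ] <- colMeans(x)
    v <- apply(x, 2, stats::var)
    if (any(v < var_floor))
      floored <- c(floored, paste0(attributes[v < var_floor], "/", cl))
    sig2[cl, ] <- pmax(v, var_floor)
  }
  if (length(floored))
    warning("variance floored for ", paste(floored, collapse = ", "))
  structure(list(classes = classes,
                 priors = as.numeric(n_by_class) / sum(n_by_class),
                 mean = mu, var = sig2,
                 attributes = attributes, var_floor = var_floor,
                 n = as.integer(n_by_class)),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("Gaussian naive Bayes: %d attributes (%s); priors DE=%.3f NDE=%.3f (n=%d+%d)\n",
              length(x$attributes), paste(x$attributes, collapse = ","),
              x$priors[1], x$priors[2], x$n[1], x$n[2]))
  invisible(x)
}

#' Posterior probability of differential expression
#'
#' Scores genes with a trained model:
#' `p(DE | f) = p(DE) prod_i phi(f_i; mu_DE,i, var_DE,i) / sum_C ...`,
#' evaluated in log space for numerical stability. Higher scores mean
#' higher posterior probability that the gene is differentially
#' expressed; `p(DE|f) + p(NDE|f) = 1`.
#'
#' @param model an `nb_model`.
#' @param features data.frame (or named vector for one gene) containing
#'   the model's attribute columns.
#' @return numeric vector of posterior DE probabilities in \[0, 1\].
#' @export
nb_score <- function(model, features) {
  if (is.null(dim(features))) features <- as.data.frame(as.list(features))
  stopifnot(all(model$attributes %in% names(features)))
  x <- as.matrix(features[, model$attributes, drop = FALSE])
  loglik <- vapply(model$classes, function(cl) {
    ll <- vapply(seq_along(model$attributes), function(j)
      stats::dnorm(x[, j], model$mean[cl, j], sqrt(model$var[cl, j]), log = TRUE),
      numeric(nrow(x)))
    rowSums(matrix(ll, nrow = nrow(x)))
  }, numeric(nrow(x)))
  loglik <- matrix(loglik, nrow = nrow(x)) +
    rep(log(model$priors), each = nrow(x))
  m <- apply(loglik, 1, max)
  post <- exp(loglik - m)
  unname(post[, 1] / rowSums(post))
}

#' Leave-one-out cross-validated scores
#'
#' Each labeled gene is scored by a model trained on all other labeled
#' genes; deterministic and invariant to row order.
#'
#' @param table labeled feature table (see [nb_train()]).
#' @param attributes attribute subset.
#' @param var_floor passed to [nb_train()].
#' @return numeric vector of LOOCV posterior DE scores, one per row.
#' @export
loocv_scores <- function(table, attributes = c("FC", "ARPK", "GCC"),
                         var_floor = 1e-9) {
  n <- nrow(table)
  stopifnot(n >= 3L)
  tab <- table(factor(table$label, levels = c("DE", "NDE")))
  if (any(tab < 3L))
    stop("leave-one-out would empty or degenerate a class; need >= 3 per class")
  vapply(seq_len(n), function(i) {
    fit <- suppressWarnings(
      nb_train(table[-i, , drop = FALSE], attributes, var_floor))
    nb_score(fit, table[i, , drop = FALSE])
  }, numeric(1))
}

#' ROC curve and tie-corrected AUC
#'
#' Genes are ranked by descending score and the decision threshold is
#' stepped one gene at a time, producing the (FPR, TPR) staircase from
#' (0,0) to (1,1). The AUC is computed by the rank (Mann-Whitney)
#' formula with midranks, so that tied scores contribute half a
#' concordance and the ordering among ties cannot change the value.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels logical (or coercible) vector, `TRUE` = positive.
#' @return list of class `roc_result` with `points` (data.frame
#'   `fpr, tpr` including the origin) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both positive and negative labels are required")
  o <- order(-scores)
  tpr <- cumsum(labels[o]) / n_pos
  fpr <- cumsum(!labels[o]) / n_neg
  # midrank Mann-Whitney AUC (tie-corrected)
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Attribute-ablation evaluation
#'
#' Retrains and re-scores with each attribute removed in turn,
#' reporting the LOOCV AUC of the full model and of each
#' one-attribute-removed model. The drop in AUC measures how much
#' signal the removed attribute carries.
#'
#' @param table labeled feature table restricted to DE/NDE rows.
#' @param attributes full attribute set.
#' @param var_floor passed to [nb_train()].
#' @return data.frame `subset, removed, auc` with rows `all` and one per
#'   removed attribute.
#' @export
ablation_run <- function(table, attributes = c("FC", "ARPK", "GCC"),
                         var_floor = 1e-9) {
  pos <- table$label == "DE"
  eval_subset <- function(attrs) {
    s <- loocv_scores(table, attrs, var_floor)
    roc_auc(s, pos)$auc
  }
  res <- data.frame(
    subset = c("all", paste0("-", attributes)),
    removed = c(NA_character_, attributes),
    auc = c(eval_subset(attributes),
            vapply(attributes, function(a)
              eval_subset(setdiff(attributes, a)), numeric(1))),
    row.names = NULL
  )
  res
}

#' Rank genes by posterior DE score
#'
#' Stable ordering: descending score, ties broken by gene id, so output
#' is reproducible; the AUC itself is tie-corrected and unaffected by
#' the tie order.
#'
#' @param gene_id character vector.
#' @param score numeric scores.
#' @return data.frame `gene_id, score, rank` sorted by rank.
#' @export
rank_gene_scores <- function(gene_id, score) {
  o <- order(-score, gene_id)
  data.frame(gene_id = gene_id[o], score = score[o],
             rank = seq_along(o), row.names = NULL)
}

#' Serialize / restore an NB model as JSON
#'
#' @param model an `nb_model`.
#' @param path JSON file path.
#' @export
nb_model_write_json <- function(model, path) {
  obj <- list(classes = model$classes, priors = model$priors,
              attributes = model$attributes,
              mean = as.data.frame(model$mean),
              var = as.data.frame(model$var),
              var_floor = model$var_floor, n = model$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname nb_model_write_json
#' @export
nb_model_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(df) {
    m <- as.matrix(df)
    dimnames(m) <- list(obj$classes, obj$attributes)
    m
  }
  structure(list(classes = obj$classes, priors = obj$priors,
                 mean = mk(obj$mean), var = mk(obj$var),
                 attributes = obj$attributes, var_floor = obj$var_floor,
                 n = as.integer(obj$n)),
            class = "nb_model")
}
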