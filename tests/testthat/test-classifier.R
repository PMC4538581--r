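make_gauss_table <- function(n_per_class, mu_de, mu_nde, sd = 0.1, seed = 1) {
  set.seed(seed)
  data.frame(
    label = rep(c("DE", "NDE"), each = n_per_class),
    FC = c(rnorm(n_per_class, mu_de[1], sd), rnorm(n_per_class, mu_nde[1], sd)),
    ARPK = c(rnorm(n_per_class, mu_de[2], sd), rnorm(n_per_class, mu_nde[2], sd)),
    GCC = c(rnorm(n_per_class, mu_de[3], sd), rnorm(n_per_class, mu_nde[3], sd))
  )
}

test_that("training recovers class parameters and priors", {
  tab <- make_gauss_table(500, c(0.3, 0.4, 0.5), c(0.7, 0.4, 0.5), sd = 0.1, seed = 2)
  m <- nb_train(tab)
  tol <- 3 * 0.1 / sqrt(500)
  expect_lt(abs(m$mean["DE", "FC"] - 0.3), tol)
  expect_lt(abs(m$mean["NDE", "FC"] - 0.7), tol)
  expect_equal(m$priors, c(0.5, 0.5))
  expect_true(all(m$var >= m$var_floor))
  # n-1 variance estimator
  expect_equal(unname(m$var["DE", "FC"]), var(tab$FC[tab$label == "DE"]))
  # attribute-subset models carry only the requested Gaussians
  m1 <- nb_train(tab, attributes = "FC")
  expect_equal(colnames(m1$mean), "FC")
  expect_error(nb_train(tab[tab$label == "DE", ]), "both DE and NDE")
})

test_that("zero-variance attributes are floored with a warning", {
  tab <- make_gauss_table(20, c(0.3, 0.4, 0.5), c(0.7, 0.4, 0.5), seed = 3)
  tab$GCC <- 0.5
  expect_warning(m <- nb_train(tab), "floored")
  expect_equal(unname(m$var[, "GCC"]), c(1e-9, 1e-9))
  expect_true(all(is.finite(nb_score(m, tab))))
})

test_that("posterior scores equal a directly evaluated Bayes-rule oracle", {
  # symmetric cases
  tab_sym <- make_gauss_table(50, c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), seed = 4)
  m_sym <- nb_train(tab_sym)
  m_sym$mean["NDE", ] <- m_sym$mean["DE", ]
  m_sym$var["NDE", ] <- m_sym$var["DE", ]
  m_sym$priors <- c(0.5, 0.5)
  expect_equal(nb_score(m_sym, data.frame(FC = 0.1, ARPK = 0.9, GCC = 0.4)), 0.5)

  m1 <- structure(list(classes = c("DE", "NDE"), priors = c(0.5, 0.5),
                       mean = matrix(c(1, 0), 2, 1, dimnames = list(c("DE", "NDE"), "FC")),
                       var = matrix(c(1, 1), 2, 1, dimnames = list(c("DE", "NDE"), "FC")),
                       attributes = "FC", var_floor = 1e-9, n = c(5L, 5L)),
                  class = "nb_model")
  expect_equal(nb_score(m1, data.frame(FC = 0.5)), 0.5)  # symmetric midpoint

  # 100 random small models vs the arithmetic oracle
  set.seed(5)
  for (i in 1:100) {
    k <- sample(1:3, 1)
    attrs <- c("FC", "ARPK", "GCC")[seq_len(k)]
    pr <- runif(1, 0.05, 0.95)
    m <- structure(list(
      classes = c("DE", "NDE"), priors = c(pr, 1 - pr),
      mean = matrix(runif(2 * k), 2, k, dimnames = list(c("DE", "NDE"), attrs)),
      var = matrix(runif(2 * k, 0.01, 0.5), 2, k, dimnames = list(c("DE", "NDE"), attrs)),
      attributes = attrs, var_floor = 1e-9, n = c(5L, 5L)), class = "nb_model")
    x <- setNames(runif(k), attrs)
    expect_equal(nb_score(m, as.data.frame(as.list(x))),
                 bf_nb_posterior(m, x), tolerance = 1e-12)
  }
})

test_that("posteriors normalize and are invariant to likelihood rescaling", {
  tab <- make_gauss_table(30, c(0.3, 0.4, 0.6), c(0.7, 0.5, 0.4), seed = 6)
  m <- nb_train(tab)
  s <- nb_score(m, tab)
  expect_true(all(s >= 0 & s <= 1))
  # p(NDE|f) via swapped classes complements p(DE|f)
  m_swap <- m
  m_swap$priors <- rev(m$priors)
  m_swap$mean <- m$mean[2:1, , drop = FALSE]; rownames(m_swap$mean) <- m$classes
  m_swap$var <- m$var[2:1, , drop = FALSE]; rownames(m_swap$var) <- m$classes
  expect_equal(s + nb_score(m_swap, tab), rep(1, nrow(tab)))
})

test_that("e1071's naiveBayes gives the same posteriors on numeric features", {
  skip_if_not_installed("e1071")
  tab <- make_gauss_table(40, c(0.3, 0.4, 0.6), c(0.7, 0.5, 0.4), seed = 7)
  m <- nb_train(tab)
  fit <- e1071::naiveBayes(tab[, c("FC", "ARPK", "GCC")], factor(tab$label))
  ref <- predict(fit, tab[, c("FC", "ARPK", "GCC")], type = "raw")[, "DE"]
  expect_equal(nb_score(m, tab), unname(ref), tolerance = 1e-9)
})

test_that("LOOCV equals explicit retrains and ignores row order", {
  tab <- make_gauss_table(3, c(0.3, 0.4, 0.6), c(0.7, 0.5, 0.4), sd = 0.05, seed = 8)
  s <- loocv_scores(tab)
  for (i in seq_len(nrow(tab))) {
    fit <- nb_train(tab[-i, ])
    expect_equal(s[i], nb_score(fit, tab[i, ]))
  }
  perm <- sample(nrow(tab))
  expect_equal(loocv_scores(tab[perm, ]), s[perm])
  # duplicated rows score identically
  tab2 <- rbind(tab, tab[1, ])
  s2 <- loocv_scores(tab2)
  expect_equal(s2[1], s2[nrow(tab2)])
  expect_error(loocv_scores(tab[c(1, 2, 4, 5, 6), ]), ">= 3 per class")
})

test_that("ROC stepping yields a monotone staircase and tie-corrected AUC", {
  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # brute-force pair-counting oracle on 200 random instances incl. ties
  set.seed(9)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, bf_pair_auc(scores, labels))
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both")
})

test_that("random scores give chance-level AUC", {
  set.seed(10)
  n <- 2000
  r <- roc_auc(runif(n), runif(n) > 0.5)
  expect_lt(abs(r$auc - 0.5), 0.04)
})

test_that("ablation identifies the attribute carrying the signal", {
  # only FC differs between classes by construction; 200 per class keeps
  # the LOOCV pessimism on the pure-noise subset small
  tab <- make_gauss_table(200, c(0.3, 0.5, 0.5), c(0.8, 0.5, 0.5), sd = 0.05, seed = 11)
  ab <- ablation_run(tab)
  expect_equal(ab$subset, c("all", "-FC", "-ARPK", "-GCC"))
  auc_all <- ab$auc[ab$subset == "all"]
  expect_lt(abs(ab$auc[ab$subset == "-FC"] - 0.5), 0.15)
  expect_gt(auc_all, 0.95)
  expect_true(all(auc_all >= ab$auc[-1] - 1e-9))
  # the full subset equals the default evaluation
  expect_equal(auc_all, roc_auc(loocv_scores(tab), tab$label == "DE")$auc)
})

test_that("model serialization round-trips through JSON", {
  tab <- make_gauss_table(20, c(0.3, 0.4, 0.6), c(0.7, 0.5, 0.4), seed = 12)
  m <- nb_train(tab)
  path <- tempfile(fileext = ".json")
  nb_model_write_json(m, path)
  m2 <- nb_model_read_json(path)
  expect_equal(m2$mean, m$mean)
  expect_equal(m2$var, m$var)
  expect_equal(m2$priors, m$priors)
  expect_equal(nb_score(m2, tab), nb_score(m, tab))
})

test_that("gene ranking is stable under score ties", {
  rk <- rank_gene_scores(c("b", "a", "c"), c(0.5, 0.5, 0.9))
  expect_equal(rk$gene_id, c("c", "a", "b"))
  expect_equal(rk$rank, 1:3)
})
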