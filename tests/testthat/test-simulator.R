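test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 33, n_genes = 6, length_range = c(200L, 300L),
                    lambda_range = c(0.5, 1.5), replicates = 1,
                    spike_fraction = 0.3)
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  t1 <- simulate_uniform_reads(cfg, d1)
  t2 <- simulate_uniform_reads(cfg, d2)
  expect_identical(t1$genes, t2$genes)
  expect_identical(t1$depth, t2$depth)
  for (s in names(t1$sam))
    expect_identical(readLines(t1$sam[[s]]), readLines(t2$sam[[s]]))
  expect_identical(readLines(t1$gtf), readLines(t2$gtf))
  # a different seed actually changes the output
  t3 <- simulate_uniform_depths(sim_config(seed = 34, n_genes = 6,
                                           length_range = c(200L, 300L),
                                           lambda_range = c(0.5, 1.5),
                                           replicates = 1))
  expect_false(identical(t1$depth[["c1_r1"]], t3$depth[["c1_r1"]]))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(3)
  set.seed(99)
  invisible(simulate_uniform_depths(sim_config(seed = 1, n_genes = 3,
                                               length_range = c(100L, 120L),
                                               read_length = 35L, replicates = 1)))
  expect_identical(runif(3), a)
})

test_that("emitted SAM/GTF round-trip through annotation and counting exactly", {
  cfg <- sim_config(seed = 44, n_genes = 8, length_range = c(200L, 400L),
                    lambda_range = c(0.5, 1.5), replicates = 2,
                    n_exons = c(2L, 5L), de_fraction = 0.25)
  tr <- simulate_uniform_reads(cfg)
  models <- parse_annotation(tr$gtf)
  expect_equal(sort(names(models)), sort(tr$genes$gene_id))
  expect_equal(vapply(models, `[[`, integer(1), "TL")[tr$genes$gene_id],
               setNames(tr$genes$TL, tr$genes$gene_id))
  for (s in tr$samples$sample_id) {
    ds <- build_depth_vectors(tr$sam[[s]], models, s)
    for (g in tr$genes$gene_id)
      expect_identical(as.integer(ds$depth[[g]]),
                       as.integer(tr$depth[[s]][[g]]))
    expect_equal(unname(ds$R[tr$genes$gene_id]),
                 unname(tr$R[, s]))
  }
})

test_that("uniform placement gives Poisson per-position counts", {
  cfg <- sim_config(seed = 66, n_genes = 60, length_range = c(1500L, 1500L),
                    lambda_range = c(2, 2), replicates = 1)
  tr <- simulate_uniform_depths(cfg)
  n_adm <- 1500L - cfg$read_length + 1L
  pvals <- vapply(tr$depth[["c1_r1"]], function(r) {
    x <- r[seq_len(n_adm)]  # admissible start positions only
    lam <- mean(x)
    kmax <- max(x)
    probs <- dpois(0:kmax, lam)
    probs[kmax + 1] <- probs[kmax + 1] + ppois(kmax, lam, lower.tail = FALSE)
    obs <- tabulate(x + 1L, nbins = kmax + 1L)
    # pool sparse bins to keep expected counts reasonable
    keep <- probs * n_adm >= 5
    if (any(!keep)) {
      obs <- c(obs[keep], sum(obs[!keep]))
      probs <- c(probs[keep], sum(probs[!keep]))
    }
    suppressWarnings(chisq.test(obs, p = probs / sum(probs))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("spike injection is confined to chosen genes in condition 1", {
  cfg <- sim_config(seed = 77, n_genes = 10, length_range = c(300L, 300L),
                    lambda_range = c(1, 1), replicates = 1, spike_fraction = 0.2)
  tr <- simulate_uniform_depths(cfg)
  expect_equal(sum(tr$genes$spiked), 2L)
  for (g in tr$genes$gene_id[tr$genes$spiked]) {
    sp <- tr$spike_depth[["c1_r1"]][[g]]
    expect_equal(sum(sp > 0), cfg$spike_width)
    expect_true(all(sp[sp > 0] == round(cfg$spike_height * 1)))
    expect_null(tr$spike_depth[["c2_r1"]][[g]])
    # true log2fc stays the unspiked value
    expect_equal(tr$genes$log2fc[tr$genes$gene_id == g], 0)
  }
  # zero spike fraction is the identity
  tr0 <- simulate_uniform_depths(sim_config(seed = 78, n_genes = 5, replicates = 1))
  expect_identical(inject_spikes(tr0), tr0)
})

test_that("a spike inflates the raw fold change and the clamp rescues it", {
  cfg <- sim_config(seed = 88, n_genes = 20, length_range = c(300L, 300L),
                    lambda_range = c(2, 2), replicates = 1,
                    spike_fraction = 0.05)  # exactly one spiked gene
  tr <- simulate_uniform_depths(cfg)
  g <- tr$genes$gene_id[tr$genes$spiked]
  expect_length(g, 1L)
  raw1 <- sum(tr$depth[["c1_r1"]][[g]]); raw2 <- sum(tr$depth[["c2_r1"]][[g]])
  expect_gt(abs(log2(raw1 / raw2)), 1)
  n1 <- local_normalize(tr$depth[["c1_r1"]][[g]])$R0
  n2 <- local_normalize(tr$depth[["c2_r1"]][[g]])$R0
  expect_lt(abs(log2(n1 / n2)), 0.7)
})

test_that("training-table generator honors labels and thresholds", {
  tt <- simulate_training_table(40, 60, seed = 3)
  expect_equal(table(tt$label)[["DE"]], 40L)
  expect_equal(table(tt$label)[["NDE"]], 60L)
  expect_equal(unname(label_from_log2fc(abs(tt$true_log2fc))), unname(tt$label))
  expect_true(all(tt$FC > 0 & tt$FC <= 1))
  expect_true(all(tt$ARPK > 0 & tt$ARPK <= 1))
  expect_true(all(tt$GCC > 0 & tt$GCC <= 1))
  # attributes computed through the package's own formulas
  expect_equal(tt$FC, fold_change_attribute(tt$M1, tt$M2))
  expect_equal(tt$ARPK, arpk_attribute(tt$M1, tt$M2, tt$TL))
  # deterministic under the seed
  expect_identical(tt, simulate_training_table(40, 60, seed = 3))
})

test_that("training tables can mirror the reference class balance", {
  tt <- simulate_training_table(1966, 3388, seed = 17)
  expect_equal(sum(tt$label == "DE"), 1966L)
  expect_equal(sum(tt$label == "NDE"), 3388L)
})

test_that("configs are validated", {
  expect_error(sim_config(seed = 1, read_length = 500L,
                          length_range = c(100L, 300L)),
               "read_length")
  expect_error(sim_config(seed = 1, de_fraction = 2), "de_fraction")
})
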