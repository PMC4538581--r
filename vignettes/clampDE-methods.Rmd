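---
title: "Local normalization and naive Bayes scoring of RNA-seq differential expression"
author: "clampDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local normalization and naive Bayes scoring of RNA-seq differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampDE)
```

## The problem

Bulk RNA-seq read coverage along a transcript is usually modelled as
uniform: a read is equally likely to start at any position. Real
libraries violate this in a specific, troublesome way — occasionally a
very narrow window (tens of bases) accumulates a very tall stack of
read starts in one sample but not in another. Because differential
expression is computed from total gene counts, one such peak can more
than double a gene's apparent expression and create a false positive
fold change for a gene that is not differentially expressed at all.
These peaks are not explained by GC composition: the reads inside them
have the same nucleotide profile as the gene's other reads (a
diagnostic this package reproduces, see
`peak_nucleotide_profile()`), so sequence-bias corrections do not
remove them.

clampDE addresses the artifact at the position level, then scores
genes with a small supervised classifier.

## The model

### Local normalization

For one gene in one sample, let $r_i$ be the number of reads whose
leftmost aligned base maps to transcript position $i$,
$i = 1, \dots, n$ with $n$ the union-exon transcript length (TL), and
$R = \sum_i r_i$. Under uniform placement the $r_i$ are modelled as
i.i.d. Poisson with mean

$$\lambda_T = \frac{1}{n} \sum_{i=1}^n r_i ,$$

the mean over *all* positions, zeros included. The clamp bounds are the
exact quantiles of this fitted Poisson: the upper confidence limit
$\mathrm{UCL} = Q_{\text{Pois}(\lambda_T)}(0.975)$ and the lower limit
$\mathrm{LCL} = Q_{\text{Pois}(\lambda_T)}(0.025)$, the two sides of a
central 95% band. Each count is corrected to

$$r_i^0 = \begin{cases}\mathrm{UCL} & r_i > \mathrm{UCL}\\
\mathrm{LCL} & r_i < \mathrm{LCL}\\ r_i & \text{otherwise,}\end{cases}
\qquad R_0 = \sum_i r_i^0 ,$$

and $R_0$ replaces $R$ downstream. Two choices here deserve emphasis.
First, the band is on the *distribution of the counts*, not a
confidence interval for the $\lambda_T$ estimator: the clamp acts on
individual $r_i$, so exact Poisson quantiles (no normal approximation)
are used — at the small $\lambda_T$ typical of per-position depth the
normal approximation is poor. Second, "discarded reads" counts only
the upper clamping, $\sum_i \max(0, r_i - \mathrm{UCL})$; lower
clamping *adds* phantom reads and is tracked separately, so $R_0 > R$
is possible (and logged) when $\lambda_T$ is large enough that
$\mathrm{LCL} > 0$.

A 100-read spike at one position of an otherwise empty 100-position
transcript gives $\lambda_T = 1$, $\mathrm{UCL} = 3$: the spike
collapses to 3 reads and 97% of the gene's reads are discarded. On
uniformly placed reads the same transform is nearly inert — that
contrast is the method's justification, and both halves are tested.

The clamp is applied per transcript (union of all exons), not per
exon. A Poisson per position within one transcript in one sample is
assumed adequate; overdispersed alternatives (negative binomial) model
between-replicate variation, which is not what the clamp targets.

### Global normalization and filtering

Clamped totals are made comparable between libraries by size factors:
median-of-ratios (each sample's median ratio of counts to the per-gene
geometric mean; the default) or TMM (trimmed mean of M-values,
computed by edgeR and converted to effective size factors with
geometric mean 1). Both are exposed because either is defensible here;
results at typical depths differ little. After normalization, genes
whose mean count is below 5 in **both** conditions are removed — too
few reads to say anything either way.

### Three bounded attributes

Each surviving gene is summarized by three attributes, each mapped
into $(0, 1]$ so they share a scale:

* **FC** $= 1 / (1 + |\log_2 (M_1 + 1)/(M_2 + 1)|)$ with $M_c$ the
  mean normalized count in condition $c$; 1 means no change. The
  absolute value is required for the stated range (a ratio below 1
  would otherwise push the attribute above 1); the pseudocount of 1
  guards zeros and is negligible past the mean-5 filter.
* **ARPK** $= 1 / (1 + \max(0, \log_2(1000 (M_1 + M_2) / (2\,
  \mathrm{TL}))))$ — reads per kilobase, log-transformed and floored
  at 0 before inversion so genes below one read per kilobase saturate
  at 1 (an `abs` variant of the floor is available via
  `arpk_mode = "abs"`).
* **GCC** $= 1 / (1 + c / C)$, the gene's mean read GC fraction $c$
  relative to the global mean $C$, computed from the raw assigned
  reads of both conditions pooled (before clamping — it describes the
  reads that mapped, not the corrected depths). A gene matching the
  global composition scores 0.5.

### Naive Bayes scoring

A Gaussian naive Bayes classifier is trained on genes labeled `DE` or
`NDE` (reference labels from $|\log_2$ fold change$|$ thresholds: DE
above 1.5, NDE below 0.5, no-call between; no-call genes are excluded
from training and scored with the full model). Priors are class
frequencies; per class and attribute a univariate Gaussian is fitted
by maximum likelihood (variance with the $n-1$ denominator, floored at
$10^{-9}$ so a degenerate training column cannot produce infinite
densities). The posterior

$$p(\mathrm{DE} \mid f_1, f_2, f_3) =
\frac{p(\mathrm{DE}) \prod_i \phi(f_i; \mu_{\mathrm{DE},i},
\sigma^2_{\mathrm{DE},i})}{\sum_{C} p(C) \prod_i \phi(f_i; \mu_{C,i},
\sigma^2_{C,i})}$$

is evaluated in log space and returned as the gene's score in
$[0, 1]$. Evaluation uses leave-one-out cross-validation and ROC/AUC:
genes are ranked by descending score and the threshold stepped one
gene at a time; the AUC itself is computed by the midrank
(Mann–Whitney) formula, so tied scores contribute half a concordance
and the tie order cannot move the value. Ranked output breaks score
ties by gene id for byte-reproducibility. `ablation_run()` retrains
with each attribute removed to measure how much signal each carries.

## What the simulator emulates

`sim_config()` / `simulate_uniform_reads()` generate two-condition
experiments under the model's own null: per gene, total reads Poisson
with mean $\lambda \cdot \mathrm{TL}$, start positions i.i.d. uniform
over the admissible starts, read sequences drawn from a per-gene base
composition. On top of that it can inject the artifact being studied —
a spike of `spike_height` $\times\ \lambda$ extra read starts over
`spike_width` consecutive positions in condition 1 only, optionally
with a GC-shifted composition — and true fold changes for a DE
fraction. Ground truth (per-position counts, spike locations, true
log2 fold changes) is returned alongside the emitted SAM/GTF, and the
SAM round-trips exactly through the package's own counting, which is
what makes end-to-end assertions possible.

Defaults are the reference simulation conditions: lengths uniform in
1000–3000 bp, per-position rate log-uniform in 0.5–4, 35 bp reads,
spikes 10 bp wide and 50× the expected depth. What the simulator does
**not** model: sequencing errors and quality variation, fragment-level
(paired) structure, positional 5'/3' bias, isoform mixtures,
overdispersion between biological replicates, and multimapping.
Passing tests therefore demonstrate correctness of the machinery and
behavior under the stated model, not performance on any real library.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GTF/GFF3's 1-based
  inclusive convention is converted only at the I/O boundary. The
  transcript coordinate concatenates union exons in ascending genomic
  order for both strands — the clamp is orientation-invariant, so
  strand flipping would add risk without changing any result.
* A gene's model is the union of all exons of all isoforms;
  isoform-level lengths are out of scope (a known limitation for genes
  expressing a short isoform of a long annotated gene, which the
  length correction then over-penalizes).
* Read assignment uses the union rule: a read counts only if its
  aligned blocks overlap exactly one gene's union exons; multimappers
  (NH > 1, or MAPQ 0 when NH is absent) and secondary alignments are
  discarded; counting is unstranded; mates are independent read-start
  events.
* `poisson_quantile` follows the standard quantile definition
  (smallest $k$ with CDF $\ge p$); a brute-force CDF-summation oracle
  checks it in the tests.
* Clamped counts stay integers (the bounds are integer quantiles);
  downstream treats them as counts.
* The clamp is *not* idempotent — re-estimating $\lambda_T$ on the
  clamped vector can shift the quantiles — and no such claim is made;
  the tested invariant is that each $r^0_i$ lies in
  $[\min(r_i, \mathrm{LCL}), \max(r_i, \mathrm{UCL})]$ and that
  widening the band monotonically shrinks the correction, reaching
  identity as the band approaches (0, 1).
* LOOCV requires at least three examples per class so that every
  removal leaves a trainable (two per class) set.

## Problem sizes used in the checks

The test suite and the acceptance script size their simulations to what
the laptop-scale generator supports while keeping the statistics
meaningful: the uniform-placement survey uses 10,000 genes (where the
fraction of genes losing more than 10% of reads to the clamp is
expected to be essentially zero); classifier parameter recovery and the
strong-effect LOOCV benchmark use 500 genes per class; SAM round-trip
and pipeline tests use tens of genes with hundreds of reads each.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42, n_genes = 40, length_range = c(300L, 400L),
                  lambda_range = c(1.5, 2.5), replicates = 2,
                  de_fraction = 0.25, spike_fraction = 0.1)
truth <- simulate_uniform_reads(cfg, dir = "sim")
sam <- split(unname(truth$sam), truth$samples$condition)
training <- simulate_training_table(500, 500, seed = 43)
res <- run_pipeline(sam, truth$gtf, training)
head(res$scores)
cmp <- report_with_without_localnorm(sam, truth$gtf)
cmp[truth$genes$spiked[match(cmp$gene_id, truth$genes$gene_id)], ]
```

The comparison table shows, for each spiked gene, the inflated
`log2FC_without` next to the rescued `log2FC_with`; the ranked score
table puts true DE genes above spiked non-DE genes once the clamp is
on.

## Known limitations

Beyond the simulator's scope listed above: the classifier is trained
on labeled data and inherits their biases; attributes are assumed
conditionally independent given the class (the naive assumption); the
Poisson band can over-trim genes with genuine sharp coverage structure
(e.g. tiny exons expressed from an unannotated short isoform); and
per-exon (rather than per-transcript) clamping is a possible extension
that is not implemented.
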