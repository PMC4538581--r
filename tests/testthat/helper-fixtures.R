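# In-code fixtures and independent oracles shared across test files.

write_toy_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_exon <- function(chrom, start1, end1, gene, strand = "+") {
  sprintf('%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
          chrom, start1, end1, strand, gene, gene)
}

# minimal SAM writer: reads = data.frame(qname, flag, chrom, pos (1-based),
# mapq, cigar, seq, nh); nh = NA omits the tag
write_toy_sam <- function(reads, chrom_lens) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), chrom_lens))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    line <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                    r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar,
                    r$seq, strrep("I", nchar(r$seq)))
    if (!is.na(r$nh)) line <- paste0(line, sprintf("\tNH:i:%d", r$nh))
    line
  }, character(1))
  writeLines(c(header, body), path)
  path
}

toy_read <- function(qname, chrom, pos, cigar, seq, flag = 0L, mapq = 60L, nh = 1L) {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, nh = nh,
             stringsAsFactors = FALSE)
}

# ---- independent oracles ------------------------------------------------

# Poisson quantile by explicit CDF summation
bf_poisson_quantile <- function(lambda, p) {
  if (lambda == 0) return(0L)
  k <- 0L
  acc <- dpois(0L, lambda)
  while (acc < p) {
    k <- k + 1L
    acc <- acc + dpois(k, lambda)
  }
  k
}

# AUC by exhaustive pair counting: (concordant + 0.5 * ties) / (n+ * n-)
bf_pair_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Bayes-rule posterior evaluated directly (no log space)
bf_nb_posterior <- function(model, x) {
  lik <- vapply(model$classes, function(cl) {
    model$priors[match(cl, model$classes)] *
      prod(dnorm(x[model$attributes], model$mean[cl, ], sqrt(model$var[cl, ])))
  }, numeric(1))
  unname(lik[1] / sum(lik))
}

# TMM factor for one sample against a reference column, from the
# definition of the weighted trimmed mean of M-values
bf_tmm_one <- function(obs, ref, trim_M = 0.30, trim_A = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_M) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_A) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
}
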