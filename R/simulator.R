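#' Simulation configuration
#'
#' Bundles the parameters of the synthetic RNA-seq generator. The
#' generator emulates the uniform-random read placement assumed by read
#' simulators — per gene and sample the total read count is Poisson
#' with mean `lambda * TL` and start positions are i.i.d. uniform over
#' the admissible starts — optionally overlaid with localized depth
#' spikes (the non-randomly positioned peak artifact) and true fold
#' changes between two conditions.
#'
#' Defaults encode the reference simulation conditions: gene lengths
#' uniform in 1000-3000 bp, per-position rate lambda log-uniform in
#' 0.5-4, 35 bp reads (the read length of the human reference training
#' libraries), spike width 10 bp and spike height 50x the expected
#' per-position depth (a very narrow, very tall peak), per-gene read GC
#' drawn around 0.5.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_genes number of genes.
#' @param length_range gene length range (bases), sampled uniformly.
#' @param lambda_range per-position read-start rate range, sampled
#'   log-uniformly.
#' @param read_length read length in bases.
#' @param replicates replicates per condition (two conditions).
#' @param de_fraction fraction of genes differentially expressed.
#' @param de_lfc range of |log2 fold change| for DE genes (uniform);
#'   non-DE genes have true log2 fold change 0.
#' @param spike_fraction fraction of genes receiving a depth spike in
#'   condition 1.
#' @param spike_width spike width in bases.
#' @param spike_height spike height as a multiple of the gene's
#'   expected per-position depth.
#' @param spike_gc_shift added to the GC probability of bases in spike
#'   reads (for validating peak composition diagnostics).
#' @param gc_mean,gc_sd per-gene read GC composition distribution
#'   (normal, truncated to \[0.2, 0.8\]).
#' @param n_exons exons per gene (1 = single-exon default; ranges up to
#'   5 exercise spliced coordinates).
#' @param intron_length intron length between exons (multi-exon mode).
#' @param gene_gap intergenic gap on the simulated chromosome.
#' @param chrom simulated chromosome name.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 1000L,
                       length_range = c(1000L, 3000L),
                       lambda_range = c(0.5, 4),
                       read_length = 35L,
                       replicates = 2L,
                       de_fraction = 0,
                       de_lfc = c(2, 4),
                       spike_fraction = 0,
                       spike_width = 10L,
                       spike_height = 50,
                       spike_gc_shift = 0,
                       gc_mean = 0.5, gc_sd = 0.05,
                       n_exons = 1L,
                       intron_length = 100L,
                       gene_gap = 500L,
                       chrom = "simchr") {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_genes >= 1L, all(length_range > 0), diff(length_range) >= 0,
            all(lambda_range > 0), read_length >= 1L, replicates >= 1L,
            de_fraction >= 0, de_fraction <= 1,
            spike_fraction >= 0, spike_fraction <= 1,
            spike_width >= 1L, spike_height > 0,
            all(n_exons >= 1L), all(n_exons <= 5L))
  if (read_length > length_range[1L])
    stop("read_length exceeds the minimum gene length")
  structure(as.list(environment()), class = "sim_config")
}

# run expr with a private RNG stream seeded by `seed`; caller's RNG
# state is untouched
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate ground-truth depth vectors under uniform read placement
#'
#' The fast core of the generator: draws gene properties and, per gene
#' and sample, a Poisson total read count placed i.i.d. uniformly over
#' the admissible start positions `[0, TL - read_length]`. Spikes (if
#' `spike_fraction > 0`) are injected into condition 1 via
#' [inject_spikes()]. No files are written; use
#' [simulate_uniform_reads()] for SAM/GTF output.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_truth`: `config`; `genes` (data.frame with
#'   `gene_id, TL, lambda, gc, log2fc, is_de, spiked, spike_start`);
#'   `models` (named list of `gene_model`); `samples` (data.frame
#'   `sample_id, condition`); `depth` (per sample, named list of
#'   per-gene base depth vectors, spikes included); `spike_depth`
#'   (same shape, the spike-only component); `R` (genes x samples
#'   matrix of totals).
#' @export
simulate_uniform_depths <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_genes
    gene_id <- sprintf("g%04d", seq_len(n))
    TL <- .sample_lengths(cfg, n)
    lambda <- exp(stats::runif(n, log(cfg$lambda_range[1L]), log(cfg$lambda_range[2L])))
    gc <- pmin(0.8, pmax(0.2, stats::rnorm(n, cfg$gc_mean, cfg$gc_sd)))
    is_de <- stats::runif(n) < cfg$de_fraction
    log2fc <- ifelse(is_de,
                     sample(c(-1, 1), n, replace = TRUE) *
                       stats::runif(n, cfg$de_lfc[1L], cfg$de_lfc[2L]),
                     0)
    samples <- data.frame(
      sample_id = paste0("c", rep(1:2, each = cfg$replicates), "_r",
                         rep(seq_len(cfg$replicates), 2L)),
      condition = rep(c("cond1", "cond2"), each = cfg$replicates)
    )
    models <- .layout_models(cfg, gene_id, TL)
    depth <- vector("list", nrow(samples))
    names(depth) <- samples$sample_id
    for (s in seq_len(nrow(samples))) {
      side <- if (samples$condition[s] == "cond1") 0.5 else -0.5
      rate <- lambda * 2^(side * log2fc)
      depth[[s]] <- stats::setNames(vector("list", n), gene_id)
      for (g in seq_len(n)) {
        n_start <- TL[g] - cfg$read_length + 1L
        N <- stats::rpois(1L, rate[g] * TL[g])
        r <- integer(TL[g])
        if (N > 0L) {
          starts <- sample.int(n_start, N, replace = TRUE)
          r <- tabulate(starts, nbins = TL[g])
        }
        depth[[s]][[g]] <- r
      }
    }
    truth <- structure(
      list(config = cfg,
           genes = data.frame(gene_id = gene_id, TL = TL, lambda = lambda,
                              gc = gc, log2fc = log2fc, is_de = is_de,
                              spiked = FALSE, spike_start = NA_integer_),
           models = models, samples = samples,
           depth = depth,
           spike_depth = NULL),
      class = "sim_truth")
    if (cfg$spike_fraction > 0) truth <- inject_spikes(truth)
    truth$R <- .truth_totals(truth)
    truth
  })
}

.sample_lengths <- function(cfg, n) {
  as.integer(round(stats::runif(n, cfg$length_range[1L], cfg$length_range[2L])))
}

# place genes end to end on one chromosome, optionally split into exons
.layout_models <- function(cfg, gene_id, TL) {
  n_ex <- if (length(cfg$n_exons) == 1L) rep(cfg$n_exons, length(TL))
          else sample(seq(cfg$n_exons[1L], cfg$n_exons[2L]), length(TL), replace = TRUE)
  pos <- 0L
  models <- vector("list", length(TL))
  for (g in seq_along(TL)) {
    k <- n_ex[g]
    # split TL into k exon lengths as evenly as possible
    base <- TL[g] %/% k
    lens <- rep(base, k)
    lens[seq_len(TL[g] - base * k)] <- base + 1L
    starts <- integer(k); ends <- integer(k)
    p <- pos
    for (e in seq_len(k)) {
      starts[e] <- p
      ends[e] <- p + lens[e]
      p <- ends[e] + cfg$intron_length
    }
    models[[g]] <- gene_model(gene_id[g], cfg$chrom, "+", starts, ends)
    pos <- ends[k] + cfg$gene_gap
  }
  stats::setNames(models, gene_id)
}

.truth_totals <- function(truth) {
  vapply(truth$depth, function(d) vapply(d, sum, numeric(1)),
         numeric(nrow(truth$genes)))
}

#' Inject localized depth spikes into simulated truth
#'
#' Chooses `spike_fraction` of the genes and adds, in every condition-1
#' sample, `round(spike_height * lambda)` extra read starts at each of
#' `spike_width` consecutive positions starting at a random admissible
#' offset. The spike-only component is kept separately in
#' `spike_depth`, and the genes' recorded `log2fc` stays the true
#' (unspiked) value, so the bias the spike induces on the observed fold
#' change can be measured against truth. A zero spike fraction returns
#' the input unchanged.
#'
#' @param truth a `sim_truth`.
#' @param spike_fraction,spike_width,spike_height override the values
#'   in `truth$config` if given.
#' @return the modified `sim_truth`.
#' @export
inject_spikes <- function(truth, spike_fraction = NULL, spike_width = NULL,
                          spike_height = NULL) {
  cfg <- truth$config
  frac <- if (is.null(spike_fraction)) cfg$spike_fraction else spike_fraction
  width <- if (is.null(spike_width)) cfg$spike_width else spike_width
  height <- if (is.null(spike_height)) cfg$spike_height else spike_height
  if (frac == 0) return(truth)
  n <- nrow(truth$genes)
  n_spiked <- max(1L, round(frac * n))
  idx <- sample.int(n, n_spiked)
  truth$spike_depth <- lapply(truth$depth, function(d) lapply(d, function(r) NULL))
  cond1 <- truth$samples$sample_id[truth$samples$condition == "cond1"]
  for (g in idx) {
    TL <- truth$genes$TL[g]
    n_adm <- TL - cfg$read_length + 1L  # admissible read-start positions
    w <- min(width, n_adm)
    start <- sample.int(n_adm - w + 1L, 1L) - 1L
    extra <- as.integer(round(height * truth$genes$lambda[g]))
    truth$genes$spiked[g] <- TRUE
    truth$genes$spike_start[g] <- start
    gid <- truth$genes$gene_id[g]
    for (s in cond1) {
      sp <- integer(TL)
      sp[start + seq_len(w)] <- extra
      truth$spike_depth[[s]][[gid]] <- sp
      truth$depth[[s]][[gid]] <- truth$depth[[s]][[gid]] + sp
    }
  }
  truth$R <- .truth_totals(truth)
  truth
}

#' Simulate uniform reads and write SAM/GTF with ground truth
#'
#' Full-fidelity generator: runs [simulate_uniform_depths()] (spikes
#' included when configured), generates per-gene transcript sequences
#' from each gene's base composition, and writes a GTF annotation plus
#' one SAM file per sample in which every simulated read start becomes
#' an alignment record (MAPQ 60, `NH:i:1`, spliced CIGARs across
#' simulated introns). Reads belonging to a spike are drawn with the
#' configured GC shift. Output is byte-identical under a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return the `sim_truth`, extended with `gtf` (path), `sam` (named
#'   paths per sample) and per-sample `reads` data.frames
#'   (`gene_id, tstart, seq, spike`).
#' @export
simulate_uniform_reads <- function(cfg, dir = tempfile("sim")) {
  truth <- simulate_uniform_depths(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(cfg$seed + 1L, {
    rl <- cfg$read_length
    n <- nrow(truth$genes)
    tseq <- vector("list", n)
    for (g in seq_len(n)) {
      gc <- truth$genes$gc[g]
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      tseq[[g]] <- sample(names(p), truth$genes$TL[g], replace = TRUE, prob = p)
    }
    truth$gtf <- file.path(dir, "genes.gtf")
    .write_gtf(truth, truth$gtf)
    chrom_len <- max(vapply(truth$models, function(m) max(m$ends), integer(1)))
    truth$sam <- stats::setNames(
      file.path(dir, paste0(truth$samples$sample_id, ".sam")),
      truth$samples$sample_id)
    truth$reads <- vector("list", nrow(truth$samples))
    names(truth$reads) <- truth$samples$sample_id
    for (s in truth$samples$sample_id) {
      recs <- .sample_sam_records(truth, s, tseq, chrom_len)
      truth$reads[[s]] <- recs$reads
      writeLines(recs$lines, truth$sam[[s]])
    }
  })
  truth
}

.write_gtf <- function(truth, path) {
  lines <- unlist(lapply(truth$models, function(m) {
    sprintf('%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
            m$chrom, m$starts + 1L, m$ends, m$strand, m$gene_id, m$gene_id)
  }), use.names = FALSE)
  writeLines(lines, path)
}

# transcript interval [tstart, tstart+len) -> 1-based genomic pos + CIGAR
.cigar_for <- function(model, tstart, len) {
  tpos <- tstart
  remaining <- len
  ops <- character(0)
  gstart <- transcript_to_genomic(model, tstart) + 1L
  while (remaining > 0L) {
    ex <- findInterval(tpos, model$cum)
    avail <- model$cum[ex + 1L] - tpos
    take <- min(avail, remaining)
    ops <- c(ops, paste0(take, "M"))
    remaining <- remaining - take
    tpos <- tpos + take
    if (remaining > 0L) {
      gap <- model$starts[ex + 1L] - model$ends[ex]
      ops <- c(ops, paste0(gap, "N"))
    }
  }
  list(pos = gstart, cigar = paste(ops, collapse = ""))
}

.sample_sam_records <- function(truth, sample_id, tseq, chrom_len) {
  cfg <- truth$config
  rl <- cfg$read_length
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", cfg$chrom, chrom_len))
  qual <- strrep("I", rl)
  all_reads <- vector("list", nrow(truth$genes))
  gene_lines <- vector("list", nrow(truth$genes))
  counter <- 0L
  for (g in seq_len(nrow(truth$genes))) {
    gid <- truth$genes$gene_id[g]
    m <- truth$models[[gid]]
    r <- truth$depth[[sample_id]][[gid]]
    sp <- if (!is.null(truth$spike_depth)) truth$spike_depth[[sample_id]][[gid]] else NULL
    nz <- which(r > 0L)
    if (!length(nz)) next
    starts <- rep(nz - 1L, r[nz])
    n_spike_at <- if (is.null(sp)) integer(length(nz)) else sp[nz]
    is_spike <- unlist(lapply(seq_along(nz), function(i)
      c(rep(TRUE, n_spike_at[i]), rep(FALSE, r[nz[i]] - n_spike_at[i]))),
      use.names = FALSE)
    tx <- paste(tseq[[g]], collapse = "")
    seqs <- substring(tx, starts + 1L, starts + rl)
    shifted <- which(is_spike) # spike reads get the GC-shifted composition
    if (length(shifted) && cfg$spike_gc_shift != 0) {
      gc <- min(0.95, max(0.05, truth$genes$gc[g] + cfg$spike_gc_shift))
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      for (i in shifted)
        seqs[i] <- paste(sample(names(p), rl, replace = TRUE, prob = p),
                         collapse = "")
    }
    # CIGAR/pos depend only on the start position; compute once per unique start
    ust <- nz - 1L
    cgs <- lapply(ust, .cigar_for, model = m, len = rl)
    lut <- match(starts, ust)
    pos <- vapply(cgs, `[[`, numeric(1), "pos")[lut]
    cigar <- vapply(cgs, `[[`, character(1), "cigar")[lut]
    gene_lines[[g]] <- sprintf("%s_%s_r%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tNH:i:1",
                               gid, sample_id, counter + seq_along(starts),
                               cfg$chrom, pos, cigar, seqs, qual)
    counter <- counter + length(starts)
    all_reads[[g]] <- data.frame(gene_id = gid, tstart = starts,
                                 seq = seqs, spike = is_spike)
  }
  keep <- !vapply(all_reads, is.null, logical(1))
  list(lines = c(header, unlist(gene_lines[keep], use.names = FALSE)),
       reads = if (any(keep)) do.call(rbind, c(all_reads[keep], make.row.names = FALSE))
               else data.frame(gene_id = character(0), tstart = integer(0),
                               seq = character(0), spike = logical(0)))
}

#' Simulate a labeled training table of gene features
#'
#' Stand-in for an experimentally labeled training set: DE genes are
#' drawn with |log2 fold change| in `de_lfc` (default at least 2), NDE
#' genes with log2 fold change `nde_lfc` (default 0), replicate counts
#' are Poisson around the condition means, and the three attributes are
#' computed through the package's own feature formulas, so every DE row
#' satisfies the DE labeling threshold and every NDE row the NDE one.
#'
#' @param n_DE,n_NDE class sizes (each >= 2).
#' @param seed integer seed.
#' @param de_lfc range of |log2 fold change| for DE genes.
#' @param nde_lfc log2 fold change of NDE genes.
#' @param base_mean_range range of baseline mean counts (log-uniform).
#' @param replicates replicates per condition.
#' @param length_range,gc_mean,gc_sd gene length and read-GC
#'   distributions, as in [sim_config()].
#' @return data.frame `gene_id, true_log2fc, label, M1, M2, TL, c, FC,
#'   ARPK, GCC`, labels in `{"DE","NDE"}`.
#' @export
simulate_training_table <- function(n_DE, n_NDE, seed,
                                    de_lfc = c(2, 4), nde_lfc = 0,
                                    base_mean_range = c(20, 2000),
                                    replicates = 2L,
                                    length_range = c(1000L, 3000L),
                                    gc_mean = 0.5, gc_sd = 0.05) {
  stopifnot(n_DE >= 2L, n_NDE >= 2L)
  .with_seed(seed, {
    n <- n_DE + n_NDE
    label <- c(rep("DE", n_DE), rep("NDE", n_NDE))
    lfc <- c(sample(c(-1, 1), n_DE, replace = TRUE) *
               stats::runif(n_DE, de_lfc[1L], de_lfc[2L]),
             rep(nde_lfc, n_NDE))
    mu <- exp(stats::runif(n, log(base_mean_range[1L]), log(base_mean_range[2L])))
    m1 <- mu * 2^(lfc / 2)
    m2 <- mu * 2^(-lfc / 2)
    M1 <- vapply(m1, function(m) mean(stats::rpois(replicates, m)), numeric(1))
    M2 <- vapply(m2, function(m) mean(stats::rpois(replicates, m)), numeric(1))
    TL <- as.integer(round(stats::runif(n, length_range[1L], length_range[2L])))
    c_gene <- pmin(0.8, pmax(0.2, stats::rnorm(n, gc_mean, gc_sd)))
    C <- mean(c_gene)
    data.frame(
      gene_id = sprintf("t%05d", seq_len(n)),
      true_log2fc = lfc, label = label,
      M1 = M1, M2 = M2, TL = TL, c = c_gene,
      FC = fold_change_attribute(M1, M2),
      ARPK = arpk_attribute(M1, M2, TL),
      GCC = gcc_attribute(c_gene, C),
      row.names = NULL
    )
  })
}
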