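#' Union-exon gene models from GTF/GFF3 annotation
#'
#' Parses a GTF (Ensembl dialect, `gene_id "X";` attributes) or GFF3
#' (`ID=`/`Parent=` chains) annotation into one gene model per gene. All
#' exons of all isoforms of a gene are merged into a sorted, disjoint
#' union, which defines the gene's transcript coordinate system: the
#' concatenation of the union exons in ascending genomic order, positions
#' `0 .. TL-1` where `TL` is the total union-exon length. All internal
#' coordinates are 0-based half-open; the 1-based inclusive convention of
#' GTF/GFF3 is converted at the I/O boundary only.
#'
#' @param path path to a GTF or GFF3 file; format is chosen from the file
#'   extension (`.gff`, `.gff3` for GFF3, anything else read as GTF).
#' @param feature_type annotation feature rows used as exons (default
#'   `"exon"`).
#' @param gene_key GTF attribute naming the gene (default `"gene_id"`).
#'   Ignored for GFF3, where `Parent=` chains are walked up to the
#'   top-level feature.
#' @return A named list of `gene_model` objects (see [gene_model()]),
#'   one per distinct gene, sorted by gene id.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tsrc\texon\t101\t200\t.\t+\t.",
#'                  'gene_id "g1";'), gtf)
#' models <- parse_annotation(gtf)
#' models$g1$TL
#' @export
parse_annotation <- function(path, feature_type = "exon", gene_key = "gene_id") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  is_gff3 <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (is_gff3) "gff3" else "gtf"),
    error = function(e) stop("failed to parse annotation '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  meta <- S4Vectors::mcols(gr)
  exons <- gr[!is.na(meta$type) & as.character(meta$type) == feature_type]
  if (length(exons) == 0L) {
    warning("no '", feature_type, "' features in ", path)
    return(structure(list(), names = character(0)))
  }
  gene_ids <- if (is_gff3) {
    .gff3_gene_ids(gr, exons)
  } else {
    ids <- S4Vectors::mcols(exons)[[gene_key]]
    if (is.null(ids)) stop("GTF records lack the '", gene_key, "' attribute")
    as.character(ids)
  }
  keep <- !is.na(gene_ids)
  if (any(!keep)) {
    warning(sum(!keep), " exon record(s) could not be assigned to a gene; dropped")
    exons <- exons[keep]
    gene_ids <- gene_ids[keep]
  }
  models <- lapply(split(exons, gene_ids), function(ex) {
    red <- GenomicRanges::reduce(ex)  # union of possibly overlapping isoform exons
    chroms <- unique(as.character(GenomicRanges::seqnames(red)))
    if (length(chroms) > 1L)
      stop("gene spans multiple chromosomes: ", paste(chroms, collapse = ", "))
    strand <- unique(as.character(BiocGenerics::strand(ex)))
    gene_model(
      gene_id = "",  # filled below from the split names
      chrom = chroms,
      strand = if (length(strand) == 1L) strand else ".",
      # GTF/GFF 1-based inclusive -> 0-based half-open
      starts = GenomicRanges::start(red) - 1L,
      ends = GenomicRanges::end(red)
    )
  })
  for (g in names(models)) models[[g]]$gene_id <- g
  models[order(names(models))]
}

# Resolve each exon's Parent chain to the top-level feature ID (the gene).
.gff3_gene_ids <- function(gr, exons) {
  meta <- S4Vectors::mcols(gr)
  ids <- as.character(meta$ID)
  parent_of <- character(0)
  plist <- meta$Parent
  has_parent <- lengths(plist) > 0L
  parent_of <- stats::setNames(
    vapply(plist[has_parent], function(p) as.character(p)[1L], character(1)),
    ids[has_parent]
  )
  resolve <- function(p) {
    seen <- character(0)
    while (!is.na(p) && p %in% names(parent_of) && !(p %in% seen)) {
      seen <- c(seen, p)
      p <- parent_of[[p]]
    }
    p
  }
  ex_meta <- S4Vectors::mcols(exons)
  vapply(seq_along(exons), function(i) {
    p <- ex_meta$Parent[[i]]
    if (length(p) == 0L) {
      id <- ex_meta$ID[i]
      if (is.na(id)) NA_character_ else as.character(id)
    } else {
      resolve(as.character(p)[1L])
    }
  }, character(1))
}

#' Construct a union-exon gene model
#'
#' Low-level constructor used by [parse_annotation()] and the simulator.
#' Exons may be given in any order and may overlap or duplicate; they are
#' merged into a sorted disjoint union, so `TL` is invariant to input
#' order and duplication.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param starts,ends integer vectors of exon coordinates, 0-based
#'   half-open.
#' @return An object of class `gene_model`: a list with fields `gene_id`,
#'   `chrom`, `strand`, `starts`, `ends` (the union exons), `TL` (total
#'   union-exon length) and `cum` (cumulative exon lengths with a leading
#'   zero, the transcript offset of each exon).
#' @export
gene_model <- function(gene_id, chrom, strand = ".", starts, ends) {
  stopifnot(length(starts) == length(ends), all(starts < ends),
            nzchar(chrom))
  o <- order(starts)
  starts <- as.integer(starts[o]); ends <- as.integer(ends[o])
  # merge overlapping / adjacent-duplicate intervals into the union
  us <- ue <- integer(0)
  for (i in seq_along(starts)) {
    if (length(us) && starts[i] <= ue[length(ue)]) {
      ue[length(ue)] <- max(ue[length(ue)], ends[i])
    } else {
      us <- c(us, starts[i]); ue <- c(ue, ends[i])
    }
  }
  widths <- ue - us
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 starts = us, ends = ue,
                 TL = sum(widths),
                 cum = c(0L, cumsum(widths))),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d union exon(s), TL=%d\n",
              x$gene_id, x$chrom, x$strand, length(x$starts), x$TL))
  invisible(x)
}

#' Map genomic positions into a gene's transcript coordinates
#'
#' For exonic positions returns the 0-based transcript offset in
#' `[0, TL)`; intronic or outside positions return `NA`.
#'
#' @param model a `gene_model`.
#' @param gpos integer vector of genomic positions (0-based).
#' @return integer vector of transcript positions, `NA` where non-exonic.
#' @seealso [transcript_to_genomic()] for the inverse on the exonic set.
#' @export
genomic_to_transcript <- function(model, gpos) {
  idx <- findInterval(gpos, model$starts)
  out <- rep(NA_integer_, length(gpos))
  ok <- idx >= 1L & gpos < model$ends[pmax(idx, 1L)]
  out[ok] <- model$cum[idx[ok]] + (as.integer(gpos[ok]) - model$starts[idx[ok]])
  out
}

#' Map transcript positions back to genomic coordinates
#'
#' @param model a `gene_model`.
#' @param tpos integer vector of transcript positions in `[0, TL)`.
#' @return integer vector of genomic positions (0-based).
#' @export
transcript_to_genomic <- function(model, tpos) {
  stopifnot(all(tpos >= 0L & tpos < model$TL))
  idx <- findInterval(tpos, model$cum, rightmost.closed = FALSE)
  model$starts[idx] + (as.integer(tpos) - model$cum[idx])
}

# GRanges of union exons across a model set, with gene metadata column.
# Used by read assignment and kept internal.
.models_granges <- function(models) {
  n_ex <- vapply(models, function(m) length(m$starts), integer(1))
  GenomicRanges::GRanges(
    seqnames = rep(vapply(models, `[[`, character(1), "chrom"), n_ex),
    ranges = IRanges::IRanges(
      start = unlist(lapply(models, function(m) m$starts + 1L), use.names = FALSE),
      end = unlist(lapply(models, function(m) m$ends), use.names = FALSE)
    ),
    gene = rep(names(models), n_ex)
  )
}
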