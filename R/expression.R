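# Transcription over DMRs and expression ratios of genes whose promoters
# overlap DMRs.

#' Promoter interval of a gene
#'
#' Strand-oriented interval of up to `upstream` bp immediately 5' of the
#' TSS, clipped at chromosome bounds. The 1-kb default is the common
#' Arabidopsis convention.
#'
#' @param genes `GRanges` with a `tss` column (0-based), e.g. from
#'   [read_gff_genes()].
#' @param upstream Promoter extent (bp).
#' @param seqlengths Optional named chromosome lengths for right-side
#'   clipping of minus-strand promoters.
#' @return `GRanges` of promoters (same order as `genes`).
#' @export
promoter_of <- function(genes, upstream = 1000, seqlengths = NULL) {
  tss <- genes$tss
  if (is.null(tss)) tss <- gene_tss(genes)
  plus <- as.character(GenomicRanges::strand(genes)) != "-"
  s <- ifelse(plus, pmax(tss - upstream, 0), tss + 1)
  e <- ifelse(plus, tss, tss + 1 + upstream)
  if (is.null(seqlengths)) {
    si <- GenomeInfoDb_seqinfo(genes)
    if (!is.null(si)) seqlengths <- GenomeInfoDb::seqlengths(si)
  }
  if (!is.null(seqlengths) && !all(is.na(seqlengths))) {
    lim <- seqlengths[as.character(GenomicRanges::seqnames(genes))]
    e <- ifelse(is.na(lim), e, pmin(e, lim))
  }
  gr0(as.character(GenomicRanges::seqnames(genes)), s, e,
      as.character(GenomicRanges::strand(genes)))
}

#' Genes whose promoters overlap a DMR set
#'
#' @param genes `GRanges` gene models.
#' @param dmrs `GRanges` DMRs.
#' @param upstream Promoter extent (bp).
#' @return The subset of `genes` whose promoter shares >= 1 bp with any DMR.
#' @export
genes_with_dmr_promoters <- function(genes, dmrs, upstream = 1000) {
  prom <- promoter_of(genes, upstream)
  genes[IRanges::overlapsAny(prom, dmrs, minoverlap = 1L,
                             ignore.strand = TRUE)]
}

#' Unique-read counts per gene
#'
#' Counts multiplicity-weighted unique reads overlapping each gene interval
#' by >= 1 bp.
#'
#' @param genes `GRanges`.
#' @param crs A `CollapsedReadSet` (mRNA reads, cap 1).
#' @return Integer vector of counts, one per gene.
#' @export
count_gene_reads <- function(genes, crs) {
  stopifnot(inherits(crs, "CollapsedReadSet"))
  uni <- crs$reads[crs$reads$is_unique]
  hits <- GenomicRanges::findOverlaps(uni, genes, minoverlap = 1L,
                                      ignore.strand = TRUE)
  cnt <- rep(0L, length(genes))
  if (length(hits)) {
    agg <- tapply(uni$multiplicity[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    cnt[as.integer(names(agg))] <- as.integer(agg)
  }
  cnt
}

#' Per-gene log2 expression ratio (mutant / wild type)
#'
#' Counts are normalized per million mapped reads; a pseudocount on the
#' normalized scale keeps the ratio defined for unexpressed genes (two zero
#' counts give a ratio of exactly 0).
#'
#' @param counts_mut,counts_wt Per-gene unique-read counts.
#' @param total_mut,total_wt Library normalization denominators (> 0).
#' @param pseudocount Added to both normalized values (default 1).
#' @return Numeric vector of log2 ratios.
#' @export
log2_expression_ratio <- function(counts_mut, counts_wt, total_mut,
                                  total_wt, pseudocount = 1) {
  if (total_mut <= 0 || total_wt <= 0) stop("totals must be positive")
  nm <- counts_mut * 1e6 / total_mut
  nw <- counts_wt * 1e6 / total_wt
  log2((nm + pseudocount) / (nw + pseudocount))
}

#' Transcription metaplot over DMRs, per genotype
#'
#' Delegates to [metaplot()] (which is per-million normalized through
#' `total_mapped`) on identical regions for each genotype's collapsed mRNA
#' reads (cap 1).
#'
#' @param dmrs `GRanges`.
#' @param mrna_by_genotype Named list of `CollapsedReadSet`s.
#' @param ... Passed to [metaplot()].
#' @return Named list of metaplot data.frames.
#' @export
dmr_transcription_profile <- function(dmrs, mrna_by_genotype, ...) {
  lapply(mrna_by_genotype, function(crs) metaplot(dmrs, crs, ...))
}
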