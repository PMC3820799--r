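# Read-retention rules, RPKM window quantification over DMR-anchored
# windows, scaled metaplots, and rank-based group tests.

#' Collapse identical reads with a multiplicity cap
#'
#' Read identity is `(chrom, start, end, strand)` (length is implied).
#' Identical rows are merged and the summed multiplicity is capped: cap 1
#' collapses PCR/optical duplicates (ChIP / mRNA / bisulfite libraries);
#' cap 100 retains up to 100 identical sRNA reads, flattening the excess.
#' The normalization denominator `total_mapped` counts all retained
#' multiplicities, unique and multi-mapping alike.
#'
#' @param reads `GRanges` with `is_unique` and `multiplicity` columns.
#' @param cap Positive integer multiplicity cap.
#' @param assay Optional assay label carried along.
#' @return A `CollapsedReadSet`: list with `reads` (collapsed `GRanges`),
#'   `total_mapped`, `cap`, `assay`.
#' @export
collapse_duplicates <- function(reads, cap, assay = NA_character_) {
  if (cap < 1) stop("cap must be >= 1")
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(reads)),
    start = GenomicRanges::start(reads),
    end = GenomicRanges::end(reads),
    strand = as.character(GenomicRanges::strand(reads)),
    is_unique = reads$is_unique,
    multiplicity = as.numeric(reads$multiplicity))
  col <- dt[, .(is_unique = is_unique[1],
                multiplicity = min(sum(multiplicity), cap)),
            by = .(chrom, start, end, strand)]
  data.table::setorder(col, chrom, start, end, strand)
  gr <- GenomicRanges::GRanges(
    seqnames = col$chrom,
    ranges = IRanges::IRanges(start = col$start, end = col$end),
    strand = col$strand,
    is_unique = col$is_unique,
    multiplicity = as.integer(col$multiplicity),
    seqinfo = GenomeInfoDb_seqinfo(reads))
  structure(list(reads = gr,
                 total_mapped = sum(col$multiplicity),
                 cap = cap, assay = assay),
            class = "CollapsedReadSet")
}

#' Select small-RNA reads by length
#'
#' Retains reads of `min_len` to `max_len` nt inclusive, or exactly
#' `size_class` nt when given (e.g. 24 for the RdDM-diagnostic size class).
#'
#' @param reads `GRanges` read set.
#' @param min_len,max_len Inclusive length bounds (default 18-28 nt).
#' @param size_class Optional single length (nt) overriding the range.
#' @return Filtered `GRanges`; uniqueness flags preserved.
#' @export
select_srna <- function(reads, min_len = 18, max_len = 28,
                        size_class = NULL) {
  if (min_len > max_len) stop("min_len > max_len")
  w <- IRanges::width(reads)
  if (!is.null(size_class)) reads[w == size_class]
  else reads[w >= min_len & w <= max_len]
}

#' Reads per kilobase per million mapped reads over regions
#'
#' Numerator: summed multiplicity of unique reads overlapping the region by
#' at least 1 bp. Denominator: region length (bp) times `total_mapped`
#' (which for sRNA libraries counts unique plus multi-mapping reads).
#'
#' @param crs A `CollapsedReadSet`.
#' @param regions `GRanges`.
#' @return Numeric RPKM vector, one value per region.
#' @export
rpkm <- function(crs, regions) {
  stopifnot(inherits(crs, "CollapsedReadSet"))
  if (crs$total_mapped <= 0) stop("total_mapped is zero")
  if (any(IRanges::width(regions) < 1)) stop("zero-length region")
  uni <- crs$reads[crs$reads$is_unique]
  hits <- GenomicRanges::findOverlaps(uni, regions, minoverlap = 1L)
  num <- rep(0, length(regions))
  if (length(hits)) {
    agg <- tapply(uni$multiplicity[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    num[as.integer(names(agg))] <- as.numeric(agg)
  }
  num * 1e9 / (IRanges::width(regions) * crs$total_mapped)
}

#' Midpoint-anchored windows around DMRs
#'
#' Each window spans `[midpoint - flank, midpoint + flank)` with the
#' midpoint at `floor((start + end) / 2)` (0-based), clipped at chromosome
#' bounds; clipping shortens the RPKM denominator accordingly.
#'
#' @param dmrs `GRanges`.
#' @param flank Half-window (bp), default 500 for the 1000-bp window.
#' @param seqlengths Optional named chromosome lengths for clipping;
#'   defaults to the `Seqinfo` on `dmrs` when present.
#' @return `GRanges` of windows.
#' @export
dmr_windows <- function(dmrs, flank = 500, seqlengths = NULL) {
  mid <- floor((start0(dmrs) + end0(dmrs)) / 2)
  s <- pmax(mid - flank, 0)
  e <- mid + flank
  if (is.null(seqlengths)) {
    si <- GenomeInfoDb_seqinfo(dmrs)
    if (!is.null(si)) seqlengths <- GenomeInfoDb::seqlengths(si)
  }
  if (!is.null(seqlengths) && !all(is.na(seqlengths))) {
    lim <- seqlengths[as.character(GenomicRanges::seqnames(dmrs))]
    e <- ifelse(is.na(lim), e, pmin(e, lim))
  }
  gr0(as.character(GenomicRanges::seqnames(dmrs)), s, e)
}

#' Per-DMR read density in midpoint-anchored windows
#'
#' @inheritParams dmr_windows
#' @param crs A `CollapsedReadSet`.
#' @return Numeric RPKM vector, one value per DMR.
#' @export
dmr_window_density <- function(dmrs, crs, flank = 500, seqlengths = NULL) {
  rpkm(crs, dmr_windows(dmrs, flank, seqlengths))
}

#' Scaled metaplot of read density over regions
#'
#' Region bodies are scaled to `n_body_bins` bins; flanks use absolute-bp
#' bins. Each bin's density is unique-read count (multiplicity-weighted)
#' over the bin scaled to RPKM, averaged across regions with equal region
#' weight. Regions shorter than `n_body_bins` use fractional bin
#' boundaries rather than being dropped. Oriented 5'->3' for stranded
#' regions.
#'
#' @param regions `GRanges`.
#' @param crs A `CollapsedReadSet`.
#' @param n_body_bins Bins across the region body.
#' @param flank Flank width (bp) on each side.
#' @param flank_bins Bins per flank.
#' @return `data.frame`: `bin` (1..flank_bins+n_body_bins+flank_bins),
#'   `zone` (upstream/body/downstream), `value` (mean RPKM), `n_regions`.
#' @export
metaplot <- function(regions, crs, n_body_bins = 20, flank = 1000,
                     flank_bins = 10) {
  stopifnot(inherits(crs, "CollapsedReadSet"))
  if (length(regions) == 0) stop("regions must be nonempty")
  uni <- crs$reads[crs$reads$is_unique]
  rs <- start0(uni); re <- end0(uni)
  rchr <- as.character(GenomicRanges::seqnames(uni))
  mult <- uni$multiplicity
  nb <- flank_bins + n_body_bins + flank_bins
  fw <- flank / flank_bins
  vals <- matrix(0, nrow = length(regions), ncol = nb)
  for (i in seq_along(regions)) {
    cn <- as.character(GenomicRanges::seqnames(regions[i]))
    s <- start0(regions[i]); e <- end0(regions[i])
    bw <- (e - s) / n_body_bins
    # bin boundaries left->right on the reference
    bounds <- c(seq(s - flank, s, by = fw),
                s + bw * seq_len(n_body_bins),
                e + fw * seq_len(flank_bins))
    lo <- bounds[-length(bounds)]; hi <- bounds[-1]
    sel <- which(rchr == cn & re > lo[1] & rs < hi[nb])
    if (length(sel)) {
      # read j counted in bin k iff open overlap with [lo_k, hi_k)
      ov <- outer(rs[sel], hi, "<") & outer(re[sel], lo, ">")
      cnt <- colSums(ov * mult[sel])
    } else cnt <- numeric(nb)
    v <- cnt * 1e9 / ((hi - lo) * crs$total_mapped)
    if (as.character(GenomicRanges::strand(regions[i])) == "-") v <- rev(v)
    vals[i, ] <- v
  }
  zone <- rep(c("upstream", "body", "downstream"),
              c(flank_bins, n_body_bins, flank_bins))
  data.frame(bin = seq_len(nb), zone = zone, value = colMeans(vals),
             n_regions = length(regions))
}

#' Mann-Whitney U test
#'
#' Midrank tie handling; exact p-value by enumeration when
#' `length(x) + length(y) <= 12` and no ties are present, otherwise the
#' normal approximation with tie and continuity correction. Two-sided by
#' default; the location direction is reported so one-sided conventions are
#' recoverable.
#'
#' @param x,y Numeric samples, each nonempty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List: `test`, `statistic` (U for `x`), `p_value`, `n`,
#'   `direction` (sign of median(x) - median(y)), `exact`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  list(test = "Mann-Whitney U Test",
       statistic = unname(ht$statistic),
       p_value = min(ht$p.value, 1),
       n = c(length(x), length(y)),
       direction = sign(stats::median(x) - stats::median(y)),
       exact = exact)
}

#' Correlation of per-DMR H3K4 density change with CHH methylation change
#'
#' For each DMR: the window-density difference (mutant minus wild type) and
#' the weighted CHH methylation difference (wild type minus mutant, pooled
#' wild-type counts); Spearman rank correlation across DMRs.
#'
#' @param dmrs `GRanges` (>= 3).
#' @param chip_wt,chip_mut `CollapsedReadSet`s.
#' @param meth_wt_tables List of wild-type `MethylomeTable`s.
#' @param meth_mut_table Mutant `MethylomeTable`.
#' @param flank Window half-width (bp).
#' @return List: `rho` (Spearman), `n`, `table` (per-DMR data.frame with
#'   `d_rpkm`, `d_meth`).
#' @export
weighted_change_correlation <- function(dmrs, chip_wt, chip_mut,
                                        meth_wt_tables, meth_mut_table,
                                        flank = 500) {
  if (length(dmrs) < 3) stop("need at least 3 DMRs")
  d_rpkm <- dmr_window_density(dmrs, chip_mut, flank) -
    dmr_window_density(dmrs, chip_wt, flank)
  d_meth <- weighted_methylation(meth_wt_tables, dmrs, "CHH") -
    weighted_methylation(meth_mut_table, dmrs, "CHH")
  ok <- is.finite(d_rpkm) & is.finite(d_meth)
  rho <- stats::cor(d_rpkm[ok], d_meth[ok], method = "spearman")
  list(rho = rho, n = sum(ok),
       table = data.frame(d_rpkm = d_rpkm, d_meth = d_meth))
}
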