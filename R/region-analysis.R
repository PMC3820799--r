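# DMR-set comparison (overlap / Venn), gene-relative statistics
# (nearest-gene distance, TSS-relative abundance) and group-location tests.

#' Do two intervals overlap by at least `min_bp`?
#'
#' Half-open arithmetic on 0-based coordinates; abutting intervals share
#' zero bases.
#'
#' @param a,b `GRanges` (recycled pairwise) on the same chromosome
#'   namespace.
#' @param min_bp Minimum shared length (default 1).
#' @return Logical vector.
#' @export
intervals_overlap <- function(a, b, min_bp = 1) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  shared <- pmin(end0(a), end0(b)) - pmax(start0(a), start0(b))
  same & shared >= min_bp
}

#' Venn class counts over 2-3 labeled interval sets
#'
#' The union of all sets is merged into a partition of disjoint regions;
#' each merged region is assigned to the class of input sets it overlaps by
#' at least 1 bp. Class counts therefore sum to the size of the union
#' partition and identical sets fall entirely in their joint class.
#'
#' @param dmr_sets Named list of 2-3 `GRanges`, each internally
#'   non-overlapping.
#' @return Named integer vector of class counts, names like `"A"`,
#'   `"A&B"`, plus attribute `"partition"` (the merged regions with their
#'   class).
#' @export
venn_counts <- function(dmr_sets) {
  if (length(dmr_sets) < 2 || length(dmr_sets) > 3)
    stop("venn_counts expects 2 or 3 labeled sets")
  if (is.null(names(dmr_sets)) || any(names(dmr_sets) == ""))
    stop("dmr_sets must be named")
  for (nm in names(dmr_sets)) {
    gr <- dmr_sets[[nm]]
    if (length(GenomicRanges::reduce(gr)) != length(gr))
      stop("set '", nm, "' is internally overlapping; merge it first")
  }
  pooled <- GenomicRanges::reduce(do.call(
    c, lapply(unname(dmr_sets), GenomicRanges::granges)))
  member <- vapply(dmr_sets, function(gr)
    IRanges::overlapsAny(pooled, gr, minoverlap = 1L), logical(length(pooled)))
  if (length(pooled) == 1) member <- matrix(member, nrow = 1,
                                            dimnames = list(NULL, names(dmr_sets)))
  cls <- apply(member, 1, function(z)
    paste(names(dmr_sets)[z], collapse = "&"))
  all_classes <- unlist(lapply(seq_along(dmr_sets), function(k)
    utils::combn(names(dmr_sets), k, paste, collapse = "&")))
  counts <- stats::setNames(integer(length(all_classes)), all_classes)
  tab <- table(cls)
  counts[names(tab)] <- as.integer(tab)
  pooled$class <- cls
  attr(counts, "partition") <- pooled
  counts
}

#' Distance from each DMR to its nearest gene
#'
#' Edge-to-edge gap in bp; 0 when the DMR overlaps (or abuts) a gene. DMRs
#' on chromosomes without genes get `NA` with a warning.
#'
#' @param dmrs,genes `GRanges`.
#' @return Numeric vector of distances (bp), one per DMR.
#' @export
distance_to_nearest_gene <- function(dmrs, genes) {
  hits <- GenomicRanges::distanceToNearest(dmrs, genes, ignore.strand = TRUE)
  out <- rep(NA_real_, length(dmrs))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  if (anyNA(out))
    warning(sum(is.na(out)), " DMR(s) on chromosomes without genes; ",
            "distance reported as NA and excluded from tests")
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param x,y Numeric samples (NA dropped), each of length >= 2; at least
#'   one must have nonzero variance.
#' @return List: `test`, `statistic`, `df`, `p_value`, `n`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2) stop("sample x has fewer than 2 values")
  if (length(y) < 2) stop("sample y has fewer than 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both samples are degenerate (zero variance)")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(test = "Welch Two Sample t-test",
       statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = ht$p.value,
       n = c(length(x), length(y)))
}

#' Relative DMR abundance around transcription start sites
#'
#' For strand-oriented bins around each TSS, the mean per-base DMR coverage
#' across genes divided by the number of DMRs in thousands.
#'
#' @param dmrs,genes `GRanges`.
#' @param flank Half-window around the TSS (bp).
#' @param bin Bin width (bp); `2 * flank` must be a multiple.
#' @return `data.frame` with `bin_start`, `bin_mid` (bp relative to TSS,
#'   negative = upstream) and `value`.
#' @export
tss_relative_abundance <- function(dmrs, genes, flank = 2000, bin = 100) {
  if (length(dmrs) == 0) stop("zero DMRs")
  if ((2 * flank) %% bin != 0) stop("2*flank must be a multiple of bin")
  nb <- 2L * flank / bin
  cov <- GenomicRanges::coverage(dmrs)
  acc <- matrix(0, nrow = length(genes), ncol = 2L * flank)
  for (i in seq_along(genes)) {
    cn <- as.character(GenomicRanges::seqnames(genes[i]))
    if (!cn %in% names(cov)) next
    rl <- cov[[cn]]
    tss <- genes$tss[i]                     # 0-based
    lo <- tss - flank; hi <- tss + flank    # [lo, hi) 0-based
    idx1 <- pmax(lo + 1L, 1L):pmin(hi, length(rl))  # 1-based clamp
    if (length(idx1) < 1 || idx1[1] > idx1[length(idx1)]) next
    v <- numeric(2L * flank)
    offset <- idx1 - (lo + 1L) + 1L
    v[offset] <- as.numeric(rl[idx1])
    if (as.character(GenomicRanges::strand(genes[i])) == "-") v <- rev(v)
    acc[i, ] <- v
  }
  per_base <- colMeans(acc)
  bins <- rep(seq_len(nb), each = bin)
  value <- tapply(per_base, bins, mean) / (length(dmrs) / 1000)
  bin_start <- seq(-flank, flank - bin, by = bin)
  data.frame(bin_start = bin_start, bin_mid = bin_start + bin / 2,
             value = as.numeric(value))
}

#' Hierarchically cluster rows of a value matrix
#'
#' Euclidean distance, average linkage; ordering is deterministic for a
#' fixed input row order.
#'
#' @param value_matrix Numeric matrix (e.g. DMRs x genotypes), >= 2 rows,
#'   no missing values.
#' @return List: `order` (row ordering) and `hclust` (the dendrogram).
#' @export
cluster_rows <- function(value_matrix) {
  value_matrix <- as.matrix(value_matrix)
  if (nrow(value_matrix) < 2) stop("need at least 2 rows to cluster")
  if (any(!is.finite(value_matrix)))
    stop("matrix has missing/non-finite values; impute or remove rows first")
  hc <- stats::hclust(stats::dist(value_matrix, method = "euclidean"),
                      method = "average")
  list(order = hc$order, hclust = hc)
}
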