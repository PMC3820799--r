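# CHH hypomethylation DMR calling: coverage filter, kernel smoothing,
# signed site statistic with wild-type replicate variance, segmentation,
# and the four-stage filter cascade (site count, mean raw difference,
# area statistic, per-site statistic cut).

#' Default DMR-calling parameters
#'
#' All thresholds default to the published filter cascade: >= 2x coverage in
#' a majority of wild-type libraries and in the mutant; per-site statistic
#' beyond +/-2; >= 20 assayed CHH cytosines; mean raw methylation difference
#' >= 0.1; area statistic magnitude >= 100. Smoothing (tricube kernel,
#' 500 bp half-width, >= 10 sites with symmetric window expansion) and the
#' 300 bp segmentation gap are this package's documented choices.
#'
#' @param min_cov Minimum per-site coverage.
#' @param half_width Smoothing kernel half-width (bp).
#' @param min_sites_smooth Minimum sites per smoothing window.
#' @param t_cut Per-site statistic magnitude threshold.
#' @param max_gap Maximum gap (bp) between member sites of one candidate.
#' @param min_sites Minimum assayed CHH sites per DMR.
#' @param min_meandiff Minimum |mean raw methylation difference|.
#' @param min_area Minimum |sum of site statistics|.
#' @param direction `"hypo"` (default: mutant lower), `"hyper"`, or
#'   `"both"`.
#' @return Named list of parameters.
#' @export
dmr_params <- function(min_cov = 2, half_width = 500, min_sites_smooth = 10,
                       t_cut = 2, max_gap = 300, min_sites = 20,
                       min_meandiff = 0.1, min_area = 100,
                       direction = "hypo") {
  as.list(environment())
}

#' Coverage-filter CHH sites across libraries
#'
#' Retains a CHH site when its total read count is at least `min_cov` in
#' strictly more than half of the wild-type libraries AND in the mutant
#' library.
#'
#' @param wt_tables List of wild-type `MethylomeTable`s.
#' @param mut_table Mutant `MethylomeTable`.
#' @param min_cov Minimum coverage (default 2).
#' @return A `data.table` of retained CHH sites, sorted by
#'   `(chrom, pos, strand)`, with columns `mut_m`, `mut_t`, per-replicate
#'   `wt_m_<r>` / `wt_t_<r>`, raw proportions `mut_p`, `wt_p_<r>` and their
#'   replicate mean `wt_mean_p` (over replicates with nonzero coverage).
#' @export
coverage_filter <- function(wt_tables, mut_table, min_cov = 2) {
  if (length(wt_tables) == 0) stop("zero wild-type libraries")
  key <- c("chrom", "pos", "strand")
  mut <- data.table::as.data.table(mut_table)[context == "CHH",
    .(chrom, pos, strand, mut_m = meth, mut_t = total)]
  base <- mut
  R <- length(wt_tables)
  for (r in seq_len(R)) {
    w <- data.table::as.data.table(wt_tables[[r]])[context == "CHH",
      c(key, "meth", "total"), with = FALSE]
    data.table::setnames(w, c("meth", "total"),
                         paste0(c("wt_m_", "wt_t_"), r))
    base <- merge(base, w, by = key, all = TRUE)
  }
  for (cn in grep("^(wt_[mt]_|mut_[mt])", names(base), value = TRUE))
    data.table::set(base, which(is.na(base[[cn]])), cn, 0L)
  tmat <- as.matrix(base[, paste0("wt_t_", seq_len(R)), with = FALSE])
  keep <- base$mut_t >= min_cov & rowSums(tmat >= min_cov) > R / 2
  out <- base[keep]
  data.table::setorder(out, chrom, pos, strand)
  out[, mut_p := mut_m / mut_t]
  pw <- matrix(NA_real_, nrow(out), R)
  for (r in seq_len(R)) {
    tt <- out[[paste0("wt_t_", r)]]
    p <- ifelse(tt > 0, out[[paste0("wt_m_", r)]] / tt, NA_real_)
    pw[, r] <- p
    out[, (paste0("wt_p_", r)) := p]
  }
  out[, wt_mean_p := rowMeans(pw, na.rm = TRUE)]
  data.table::setattr(out, "n_wt", R)
  out[]
}

#' Smooth methylation proportions and estimate local wild-type variability
#'
#' Tricube-kernel weighted means within +/- `half_width` bp, the window
#' doubling symmetrically until at least `min_sites` retained sites are
#' included. The wild-type group track smooths the per-site replicate-mean
#' proportion; each replicate is also smoothed individually and the local SD
#' across replicate smoothed values gives `sigma`, floored downstream at its
#' genome-wide median. Chromosomes with fewer than `min_sites` retained
#' sites are emitted unsmoothed with a warning.
#'
#' @param filtered Output of [coverage_filter()].
#' @param half_width Kernel half-width (bp).
#' @param min_sites Minimum sites per window.
#' @return `data.table` with `mu_wt`, `mu_mut`, `sigma` plus carried raw
#'   proportions; attribute `sigma_floor` holds the genome-wide median
#'   local SD.
#' @export
smooth_track <- function(filtered, half_width = 500, min_sites = 10) {
  R <- attr(filtered, "n_wt")
  out <- data.table::copy(filtered)
  n <- nrow(out)
  mu_wt <- mu_mut <- numeric(n)
  smat <- matrix(NA_real_, n, R)
  for (cn in unique(out$chrom)) {
    idx <- which(out$chrom == cn)
    pos <- out$pos[idx]
    if (length(idx) < min_sites) {
      warning("chromosome ", cn, " has fewer than ", min_sites,
              " retained sites; emitted unsmoothed")
      mu_wt[idx] <- out$wt_mean_p[idx]
      mu_mut[idx] <- out$mut_p[idx]
      for (r in seq_len(R)) smat[idx, r] <- out[[paste0("wt_p_", r)]][idx]
      next
    }
    mu_wt[idx] <- smooth_tricube_cpp(pos, out$wt_mean_p[idx],
                                     half_width, min_sites)
    mu_mut[idx] <- smooth_tricube_cpp(pos, out$mut_p[idx],
                                      half_width, min_sites)
    for (r in seq_len(R))
      smat[idx, r] <- smooth_tricube_cpp(pos, out[[paste0("wt_p_", r)]][idx],
                                         half_width, min_sites)
  }
  k <- rowSums(!is.na(smat))
  rm <- rowMeans(smat, na.rm = TRUE)
  sigma <- sqrt(rowSums((smat - rm)^2, na.rm = TRUE) / pmax(k - 1, 1))
  sigma[k < 2] <- NA_real_
  out[, mu_wt := mu_wt]
  out[, mu_mut := mu_mut]
  out[, sigma := sigma]
  floor_val <- stats::median(sigma, na.rm = TRUE)
  if (!is.finite(floor_val) || floor_val <= 0) floor_val <- 1e-8
  data.table::setattr(out, "sigma_floor", floor_val)
  data.table::setattr(out, "n_wt", R)
  out[]
}

#' Per-site signed statistic
#'
#' `t = (mu_wt - mu_mut) / max(sigma, sigma_floor)`; positive when the
#' mutant is hypomethylated. Swapping the group roles negates every value.
#'
#' @param track Output of [smooth_track()].
#' @param sigma_floor Positive floor for the local SD; defaults to the
#'   track's genome-wide median.
#' @return The track with a `t_stat` column; attribute `sigma_floor` kept.
#' @export
site_statistics <- function(track, sigma_floor = attr(track, "sigma_floor")) {
  if (is.null(sigma_floor) || !is.finite(sigma_floor) || sigma_floor <= 0)
    stop("sigma_floor must be a positive number")
  out <- data.table::copy(track)
  s <- out$sigma
  s[is.na(s)] <- sigma_floor
  out[, t_stat := (mu_wt - mu_mut) / pmax(s, sigma_floor)]
  data.table::setattr(out, "sigma_floor", sigma_floor)
  out[]
}

#' Segment site statistics into candidate regions
#'
#' Candidates are maximal runs of consecutive retained sites with
#' `|t| > t_cut`, uniform sign, and inter-site gaps of at most `max_gap` bp;
#' the interval spans the first to one past the last member site.
#'
#' @param stats Output of [site_statistics()].
#' @param t_cut Statistic magnitude threshold (default 2).
#' @param max_gap Maximum gap (bp) between consecutive member sites.
#' @return `data.table` of candidates: `chrom`, `start`, `end` (0-based
#'   half-open), `n_chh`, `mean_diff` (mean raw wild-type minus mutant
#'   proportion), `area` (sum of member statistics), `direction`, and a
#'   list column `site_pos`.
#' @export
segment_candidates <- function(stats, t_cut = 2, max_gap = 300) {
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    n_chh = integer(), mean_diff = numeric(), area = numeric(),
    direction = character(), site_pos = list())
  if (nrow(stats) == 0) return(empty)
  s <- stats[order(chrom, pos)]
  pass <- abs(s$t_stat) > t_cut
  sgn <- sign(s$t_stat)
  newrun <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                sgn[-1] != sgn[-nrow(s)] |
                (s$pos[-1] - s$pos[-nrow(s)]) > max_gap |
                !pass[-1] | !pass[-nrow(s)])
  s[, run_id := cumsum(newrun)]
  cand <- s[pass, .(
    chrom = chrom[1],
    start = min(pos),
    end = max(pos) + 1L,
    n_chh = .N,
    mean_diff = mean(wt_mean_p - mut_p),
    area = sum(t_stat),
    direction = if (sign(t_stat[1]) > 0) "hypo" else "hyper",
    site_pos = list(pos)), by = run_id][, run_id := NULL]
  if (nrow(cand) == 0) return(empty)
  cand[]
}

#' Apply the final DMR filter cascade
#'
#' Retains candidates with at least `min_sites` assayed CHH cytosines,
#' `|mean_diff| >= min_meandiff` and `|area| >= min_area` (ties at the
#' thresholds retained). By default only hypomethylated regions are
#' reported.
#'
#' @param candidates Output of [segment_candidates()].
#' @param min_sites,min_meandiff,min_area Filter thresholds.
#' @param direction `"hypo"`, `"hyper"` or `"both"`.
#' @param seqinfo Optional `Seqinfo` for the result.
#' @return `GRanges` of DMRs with metadata `n_chh`, `mean_diff`, `area`,
#'   `direction`.
#' @export
filter_dmrs <- function(candidates, min_sites = 20, min_meandiff = 0.1,
                        min_area = 100, direction = "hypo",
                        seqinfo = NULL) {
  keep <- candidates$n_chh >= min_sites &
    abs(candidates$mean_diff) >= min_meandiff &
    abs(candidates$area) >= min_area
  if (direction != "both") keep <- keep & candidates$direction == direction
  kept <- candidates[keep]
  gr <- gr0(kept$chrom, kept$start, kept$end, seqinfo = seqinfo)
  gr$n_chh <- kept$n_chh
  gr$mean_diff <- kept$mean_diff
  gr$area <- kept$area
  gr$direction <- kept$direction
  gr
}

#' Call CHH hypomethylation DMRs for one mutant against a replicate group
#'
#' Composes [coverage_filter()], [smooth_track()], [site_statistics()],
#' [segment_candidates()] and [filter_dmrs()].
#'
#' @param wt_tables List of wild-type `MethylomeTable`s.
#' @param mut_table Mutant `MethylomeTable`.
#' @param params Parameter list from [dmr_params()].
#' @param seqinfo Optional `Seqinfo` for the result.
#' @return `GRanges` of DMRs with `n_chh`, `mean_diff`, `area`,
#'   `direction`.
#' @export
call_chh_dmrs <- function(wt_tables, mut_table, params = dmr_params(),
                          seqinfo = NULL) {
  filtered <- coverage_filter(wt_tables, mut_table, params$min_cov)
  track <- smooth_track(filtered, params$half_width, params$min_sites_smooth)
  stats <- site_statistics(track)
  cand <- segment_candidates(stats, params$t_cut, params$max_gap)
  filter_dmrs(cand, params$min_sites, params$min_meandiff, params$min_area,
              params$direction, seqinfo = seqinfo)
}

#' Re-verify every filter clause for a DMR set
#'
#' Recomputes, from the methylome inputs, the member sites, site count,
#' mean raw difference, area and per-site statistics of each DMR and flags
#' any violated clause.
#'
#' @param dmrs `GRanges` of DMRs.
#' @param wt_tables,mut_table Methylome inputs.
#' @param params Parameter list from [dmr_params()].
#' @return `data.table` with one row per DMR: recomputed `n_chh`,
#'   `mean_diff`, `area`, logical `pass`, and `failed` (comma-separated
#'   clause names, empty when passing).
#' @export
audit_dmrs <- function(dmrs, wt_tables, mut_table, params = dmr_params()) {
  if (length(dmrs) == 0) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      n_chh = integer(), mean_diff = numeric(), area = numeric(),
      pass = logical(), failed = character()))
  }
  filtered <- coverage_filter(wt_tables, mut_table, params$min_cov)
  track <- smooth_track(filtered, params$half_width, params$min_sites_smooth)
  stats <- site_statistics(track)
  res <- lapply(seq_along(dmrs), function(i) {
    cn <- as.character(GenomicRanges::seqnames(dmrs[i]))
    s0 <- start0(dmrs[i]); e0 <- end0(dmrs[i])
    mem <- stats[chrom == cn & pos >= s0 & pos < e0]
    fails <- character(0)
    if (nrow(mem) < params$min_sites) fails <- c(fails, "min_sites")
    md <- if (nrow(mem)) mean(mem$wt_mean_p - mem$mut_p) else NA_real_
    ar <- if (nrow(mem)) sum(mem$t_stat) else NA_real_
    if (is.na(md) || abs(md) < params$min_meandiff)
      fails <- c(fails, "min_meandiff")
    if (is.na(ar) || abs(ar) < params$min_area) fails <- c(fails, "min_area")
    if (!nrow(mem) || any(abs(mem$t_stat) <= params$t_cut))
      fails <- c(fails, "t_cut")
    if (nrow(mem) && length(unique(sign(mem$t_stat))) > 1)
      fails <- c(fails, "uniform_sign")
    data.table::data.table(chrom = cn, start = s0, end = e0,
                           n_chh = nrow(mem), mean_diff = md, area = ar,
                           pass = length(fails) == 0,
                           failed = paste(fails, collapse = ","))
  })
  data.table::rbindlist(res)
}

#' Coverage-weighted methylation over regions
#'
#' The weighted methylation of a region is the sum of methylated counts
#' divided by the sum of total counts over its sites in the requested
#' context; multiple libraries are pooled.
#'
#' @param tables A `MethylomeTable` or list of them (pooled).
#' @param regions `GRanges`.
#' @param context `"CHH"`, `"CHG"`, `"CG"` or `"all"`.
#' @return Numeric vector, one value per region (`NA` when no covered site).
#' @export
weighted_methylation <- function(tables, regions, context = "CHH") {
  if (inherits(tables, "MethylomeTable")) tables <- list(tables)
  pooled <- data.table::rbindlist(lapply(tables, function(x)
    data.table::as.data.table(x)[, .(chrom, pos, strand, context, meth,
                                     total)]))
  if (context != "all") {
    ctx <- context
    pooled <- pooled[context == ctx]
  }
  sites <- gr0(pooled$chrom, pooled$pos, pooled$pos + 1L)
  hits <- GenomicRanges::findOverlaps(sites, regions)
  m <- tapply(pooled$meth[S4Vectors::queryHits(hits)],
              S4Vectors::subjectHits(hits), sum)
  t <- tapply(pooled$total[S4Vectors::queryHits(hits)],
              S4Vectors::subjectHits(hits), sum)
  out <- rep(NA_real_, length(regions))
  idx <- as.integer(names(m))
  tv <- as.numeric(t)
  out[idx] <- ifelse(tv > 0, as.numeric(m) / tv, NA_real_)
  out
}
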