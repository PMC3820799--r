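# Coverage filter, smoother, site statistic, segmentation and filter
# cascade of the DMR caller.

test_that("coverage filter requires 2x in a strict majority of WT libraries and in the mutant", {
  pos <- c(100L, 200L, 300L)
  # site 100: WT [2,2,2,0], mut 2 -> retained (3 of 4)
  # site 200: WT [2,2,0,0], mut 5 -> dropped (2 of 4 not a majority)
  # site 300: WT [5,5,5,5], mut 1 -> dropped (mutant below 2x)
  wt_cov <- list(c(2, 2, 5), c(2, 2, 5), c(2, 0, 5), c(0, 0, 5))
  wt <- lapply(seq_along(wt_cov), function(r)
    mk_methylome(pos, meth = 0, total = wt_cov[[r]],
                 id = paste0("wt", r)))
  mut <- mk_methylome(pos, meth = 0, total = c(2, 5, 1), id = "mut")
  filt <- coverage_filter(wt, mut, min_cov = 2)
  expect_equal(filt$pos, 100L)
  expect_error(coverage_filter(list(), mut), "zero wild-type")
  # only CHH sites are considered
  wt_cg <- lapply(1:4, function(r)
    mk_methylome(pos, meth = 0, total = 5, context = "CG",
                 id = paste0("w", r)))
  mut_cg <- mk_methylome(pos, meth = 0, total = 5, context = "CG", id = "m")
  expect_equal(nrow(coverage_filter(wt_cg, mut_cg)), 0L)
})

test_that("the smoother preserves constants, handles isolated sites, and matches direct kernel evaluation on a step", {
  pos <- seq(0L, 2000L, by = 50L)
  wt <- lapply(1:2, function(r)
    mk_methylome(pos, meth = 5, total = 10, id = paste0("wt", r)))
  mut <- mk_methylome(pos, meth = 5, total = 10, id = "mut")
  track <- smooth_track(coverage_filter(wt, mut), 500, 10)
  expect_true(all(abs(track$mu_wt - 0.5) < 1e-12))
  expect_true(all(abs(track$mu_mut - 0.5) < 1e-12))

  # fewer retained sites than min_sites: emitted unsmoothed with warning
  wt1 <- lapply(1:2, function(r)
    mk_methylome(500L, meth = 3, total = 10, id = paste0("w", r)))
  mut1 <- mk_methylome(500L, meth = 7, total = 10, id = "m")
  expect_warning(tr1 <- smooth_track(coverage_filter(wt1, mut1), 500, 10),
                 "unsmoothed")
  expect_equal(tr1$mu_mut, 0.7)

  # step 0.8 -> 0.2: smoothed mutant track matches direct tricube weights
  # and is monotone non-increasing across the step
  m_step <- ifelse(pos < 1000, 8L, 2L)
  mut2 <- mk_methylome(pos, meth = m_step, total = 10, id = "m2")
  tr2 <- smooth_track(coverage_filter(wt, mut2), 500, 10)
  raw <- m_step / 10
  direct <- vapply(seq_along(pos), function(i) {
    d <- abs(pos - pos[i])
    w <- ifelse(d <= 500, (1 - (d / 501)^3)^3, 0)
    sum(w * raw) / sum(w)
  }, 0)
  expect_equal(tr2$mu_mut, direct, tolerance = 1e-12)
  expect_true(all(diff(tr2$mu_mut) <= 1e-12))
})

test_that("site statistic follows its definition and is antisymmetric under group swap", {
  tr <- mk_track(pos = c(0, 10, 20),
                 mu_wt = c(0.5, 0.5, 0.3), mu_mut = c(0.1, 0.5, 0.5),
                 sigma = 0.1, sigma_floor = 0.05)
  st <- site_statistics(tr)
  expect_equal(st$t_stat, c(4, 0, -2))
  # swapping the group roles negates every statistic
  sw <- mk_track(pos = c(0, 10, 20),
                 mu_wt = c(0.1, 0.5, 0.5), mu_mut = c(0.5, 0.5, 0.3),
                 sigma = 0.1, sigma_floor = 0.05)
  expect_equal(site_statistics(sw)$t_stat, -st$t_stat)
  # the floor takes over when local SD is smaller
  trf <- mk_track(pos = 0, mu_wt = 0.5, mu_mut = 0.1, sigma = 0.01,
                  sigma_floor = 0.1)
  expect_equal(site_statistics(trf)$t_stat, 4)
  expect_error(site_statistics(tr, sigma_floor = 0), "positive")
})

test_that("segmentation splits on sign change, gap and sub-threshold sites", {
  mk_stats <- function(pos, t) {
    dt <- mk_track(pos, mu_wt = 0.5, mu_mut = 0.1, sigma = 0.1)
    dt$t_stat <- t
    dt
  }
  one <- segment_candidates(mk_stats(c(0, 50, 100), c(2.5, 2.5, 2.5)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_chh, 3L)
  expect_equal(c(one$start, one$end), c(0L, 101L))

  three <- segment_candidates(mk_stats(c(0, 50, 100), c(2.5, -2.5, 2.5)))
  expect_equal(nrow(three), 3L)
  expect_equal(three$n_chh, c(1L, 1L, 1L))
  expect_equal(three$direction, c("hypo", "hyper", "hypo"))

  gap <- segment_candidates(mk_stats(c(0, 301), c(2.5, 2.5)), max_gap = 300)
  expect_equal(nrow(gap), 2L)
  gap2 <- segment_candidates(mk_stats(c(0, 300), c(2.5, 2.5)), max_gap = 300)
  expect_equal(nrow(gap2), 1L)

  # sub-threshold site breaks a run without joining either side
  brk <- segment_candidates(mk_stats(c(0, 50, 100), c(2.5, 1.0, 2.5)))
  expect_equal(nrow(brk), 2L)
  expect_equal(nrow(segment_candidates(mk_stats(integer(0), numeric(0)))), 0L)
})

test_that("filter cascade keeps printed-boundary candidates and rejects just-below ones", {
  cand <- function(n_chh, mean_diff, area) data.table::data.table(
    chrom = "Chr1", start = 0L, end = 1000L, n_chh = as.integer(n_chh),
    mean_diff = mean_diff, area = area,
    direction = if (mean_diff > 0) "hypo" else "hyper",
    site_pos = list(seq_len(n_chh)))
  expect_equal(length(filter_dmrs(cand(20, 0.10, 100))), 1L)
  expect_equal(length(filter_dmrs(cand(19, 0.10, 100))), 0L)
  expect_equal(length(filter_dmrs(cand(25, 0.09, 100))), 0L)
  expect_equal(length(filter_dmrs(cand(25, 0.30, 99))), 0L)
  # hyper direction suppressed by default, available on request
  expect_equal(length(filter_dmrs(cand(25, -0.30, -150))), 0L)
  expect_equal(length(filter_dmrs(cand(25, -0.30, -150),
                                  direction = "both")), 1L)
})

test_that("caller output is internally consistent, nested under tighter thresholds, and audit-clean", {
  s <- small_sim()
  p0 <- dmr_params()
  dmrs <- call_chh_dmrs(s$sim$wt, s$sim$mutants[[1]], p0,
                        seqinfo = s$g$seqinfo)
  expect_gt(length(dmrs), 0)
  # every member site has |t| > 2, so with >= 20 sites |area| > 40 always
  expect_true(all(abs(dmrs$area) > 40))
  expect_true(all(dmrs$n_chh >= 20))
  expect_true(all(abs(dmrs$mean_diff) >= 0.1))

  as_key <- function(g) paste(GenomicRanges::seqnames(g),
                              GenomicRanges::start(g),
                              GenomicRanges::end(g))
  for (p in list(dmr_params(t_cut = 3), dmr_params(min_sites = 30),
                 dmr_params(min_meandiff = 0.2),
                 dmr_params(min_area = 200))) {
    tighter <- call_chh_dmrs(s$sim$wt, s$sim$mutants[[1]], p)
    # nesting: every tighter DMR lies inside some default-threshold DMR
    expect_true(all(IRanges::overlapsAny(tighter, dmrs)))
    expect_lte(length(tighter), length(dmrs))
  }
  # threshold-only tightenings keep identical intervals (subset)
  for (p in list(dmr_params(min_sites = 30), dmr_params(min_meandiff = 0.2),
                 dmr_params(min_area = 200))) {
    tighter <- call_chh_dmrs(s$sim$wt, s$sim$mutants[[1]], p)
    expect_true(all(as_key(tighter) %in% as_key(dmrs)))
  }

  audit <- audit_dmrs(dmrs, s$sim$wt, s$sim$mutants[[1]], p0)
  expect_true(all(audit$pass))
  # a hand-edited DMR fails with the offending clause named
  fake <- GenomicRanges::shift(dmrs[1], 5e4)
  bad <- audit_dmrs(fake, s$sim$wt, s$sim$mutants[[1]], p0)
  expect_false(bad$pass)
  expect_match(bad$failed, "min_meandiff|min_sites|min_area|t_cut")
  expect_equal(nrow(audit_dmrs(dmrs[0], s$sim$wt, s$sim$mutants[[1]], p0)),
               0L)
})
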