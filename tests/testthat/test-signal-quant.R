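# Read collapsing and caps, sRNA length selection, RPKM, windows,
# metaplots, Mann-Whitney, change correlation.

test_that("duplicate collapsing respects the cap and is idempotent and order-independent", {
  dup <- mk_reads("Chr1", rep(1000, 150), rep(1024, 150))
  capped <- collapse_duplicates(dup, cap = 100)
  expect_equal(length(capped$reads), 1L)
  expect_equal(capped$reads$multiplicity, 100L)
  expect_equal(capped$total_mapped, 100)

  chip <- mk_reads("Chr1", rep(50, 3), rep(100, 3))
  expect_equal(collapse_duplicates(chip, cap = 1)$reads$multiplicity, 1L)

  distinct <- mk_reads("Chr1", c(0, 100, 200), c(50, 150, 250))
  col <- collapse_duplicates(distinct, cap = 100)
  expect_equal(length(col$reads), 3L)
  expect_equal(col$reads$multiplicity, rep(1L, 3))
  # idempotent
  again <- collapse_duplicates(col$reads, cap = 100)
  expect_equal(as.data.frame(again$reads), as.data.frame(col$reads))
  # order-independent
  set.seed(8)
  shuf <- collapse_duplicates(distinct[sample(3)], cap = 100)
  expect_equal(as.data.frame(shuf$reads), as.data.frame(col$reads))
  expect_error(collapse_duplicates(distinct, cap = 0), "cap")
})

test_that("sRNA length selection keeps 18-28 nt and exact size classes", {
  lens <- c(17, 18, 24, 28, 29)
  r <- mk_reads("Chr1", seq(0, by = 100, length.out = 5),
                seq(0, by = 100, length.out = 5) + lens)
  expect_equal(sort(IRanges::width(select_srna(r))), c(18, 24, 28))
  r2 <- mk_reads("Chr1", c(0, 100, 200), c(21, 124, 224))
  expect_equal(length(select_srna(r2, size_class = 24)), 2L)
  expect_equal(length(select_srna(r[0])), 0L)
  expect_error(select_srna(r, min_len = 30, max_len = 20), "min_len")
})

test_that("RPKM uses unique reads in the numerator, total mapped in the denominator", {
  region <- mk_intervals("Chr1", 1000, 2000)
  rs <- seq(1100, by = 50, length.out = 10)
  reads <- mk_reads("Chr1", rs, rs + 24)
  crs <- collapse_duplicates(reads, cap = 100)
  crs$total_mapped <- 1e6
  expect_equal(rpkm(crs, region), 10.0)

  region2 <- mk_intervals("Chr1", 1000, 1500)
  reads2 <- mk_reads("Chr1", rs[1:5], rs[1:5] + 24)
  crs2 <- collapse_duplicates(reads2, cap = 100)
  crs2$total_mapped <- 2e6
  expect_equal(rpkm(crs2, region2), 5.0)

  # hand-audited 6-read toy: non-unique reads excluded from the numerator
  # but counted in the denominator
  toy <- c(mk_reads("Chr1", c(1100, 1200, 1300), c(1124, 1224, 1324),
                    unique = TRUE, mult = c(1L, 2L, 1L)),
           mk_reads("Chr1", c(1400, 1500), c(1424, 1524),
                    unique = FALSE, mult = c(3L, 1L)),
           mk_reads("Chr1", 5000, 5024, unique = TRUE, mult = 1L))
  crs3 <- collapse_duplicates(toy, cap = 100)
  expect_equal(crs3$total_mapped, 9)   # 1+2+1+3+1+1
  # numerator: unique overlapping = 1+2+1 = 4; region 1 kb
  expect_equal(rpkm(crs3, region), 4 * 1e9 / (1000 * 9))

  # linearity in numerator reads at fixed total
  crs4 <- crs3
  crs4$reads$multiplicity <- crs4$reads$multiplicity * 3L
  crs4$total_mapped <- crs3$total_mapped
  expect_equal(rpkm(crs4, region), 3 * rpkm(crs3, region))
  crs0 <- crs3; crs0$total_mapped <- 0
  expect_error(rpkm(crs0, region), "total_mapped")
})

test_that("midpoint windows span +/-500 bp and clip with a corrected denominator", {
  w <- dmr_windows(mk_intervals("Chr1", 1000, 1200), flank = 500)
  expect_equal(c(GenomicRanges::start(w) - 1L, GenomicRanges::end(w)),
               c(600L, 1600L))
  # odd-width region: midpoint floors
  w2 <- dmr_windows(mk_intervals("Chr1", 100, 201), flank = 500)
  expect_equal(GenomicRanges::start(w2) - 1L, 0L)  # clipped at 0
  expect_equal(GenomicRanges::end(w2), 650L)       # floor(301/2)+500
  # clipped window denominator uses the realized length
  reads <- mk_reads("Chr1", seq(0, 600, by = 50),
                    seq(0, 600, by = 50) + 24)
  crs <- collapse_duplicates(reads, cap = 1)
  crs$total_mapped <- 1e6
  dens <- dmr_window_density(mk_intervals("Chr1", 100, 201), crs,
                             flank = 500)
  n_in <- sum(intervals_overlap(rep(w2, length(reads)), reads))
  expect_equal(dens, n_in * 1e9 / (650 * 1e6))
  # no reads anywhere -> zero densities
  crs_far <- collapse_duplicates(mk_reads("Chr2", 0, 24), cap = 1)
  expect_equal(suppressWarnings(
    dmr_window_density(mk_intervals("Chr1", 1000, 1200), crs_far)), 0)
})

test_that("metaplots localize reads, zero out empty zones, and weight regions equally", {
  region <- mk_intervals("Chr1", 10000, 12000)
  # single read inside body bin 3 (bins of 100 bp, flank 1000/10 bins)
  rd <- mk_reads("Chr1", 10210, 10240)
  crs <- collapse_duplicates(rd, cap = 1)
  prof <- metaplot(region, crs, n_body_bins = 20, flank = 1000,
                   flank_bins = 10)
  expect_equal(nrow(prof), 40L)
  expect_equal(which(prof$value > 0), 13L)  # 10 upstream bins + body bin 3

  # reads only in flanks leave every body bin at zero
  fl <- mk_reads("Chr1", c(9100, 12500), c(9130, 12530))
  prof2 <- metaplot(region, collapse_duplicates(fl, cap = 1),
                    n_body_bins = 20, flank = 1000, flank_bins = 10)
  expect_true(all(prof2$value[prof2$zone == "body"] == 0))
  expect_gt(sum(prof2$value[prof2$zone != "body"]), 0)

  # duplicating the region set leaves the profile unchanged
  prof3 <- metaplot(c(region, region), crs, n_body_bins = 20,
                    flank = 1000, flank_bins = 10)
  expect_equal(prof3$value, prof$value, tolerance = 1e-12)

  # uniform read placement gives a flat profile within Monte-Carlo noise
  set.seed(10)
  st <- sample.int(30000, 20000) - 1
  uni <- collapse_duplicates(mk_reads("Chr1", st, st + 30), cap = 100)
  regs <- mk_intervals("Chr1", c(12000, 20000), c(14000, 22000))
  prof4 <- metaplot(regs, uni, n_body_bins = 10, flank = 500,
                    flank_bins = 5)
  expect_lt(max(prof4$value) / min(prof4$value), 1.6)

  # a region shorter than the bin count still yields finite bins
  tiny <- mk_intervals("Chr1", 10000, 10010)
  prof5 <- metaplot(tiny, crs, n_body_bins = 20, flank = 100,
                    flank_bins = 5)
  expect_true(all(is.finite(prof5$value)))
})

test_that("Mann-Whitney matches enumeration exactly and approximates well at n = 8", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)   # 2 * 1/20 over C(6,3) arrangements
  expect_equal(res$p_value, mwu_enum_p(c(1, 2, 3), c(4, 5, 6)))

  same <- mann_whitney_u(c(1, 5, 9, 13), c(5, 1, 13, 9))
  expect_gt(same$p_value, 0.85)

  set.seed(3)
  x <- rnorm(8); y <- rnorm(8) + 0.8
  approx <- mann_whitney_u(x, y)   # n1+n2 = 16 -> normal approximation
  expect_false(approx$exact)
  expect_lt(abs(approx$p_value - mwu_enum_p(x, y)), 0.02)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("weighted change correlation is +/-1 on monotone pairings and near 0 when permuted", {
  set.seed(6)
  n <- 12
  starts <- seq(1000, by = 5000, length.out = n)
  dmrs <- mk_intervals("Chr1", starts, starts + 1000)
  # methylation difference increasing across DMRs
  pos <- unlist(lapply(starts, function(s) s + seq(0, 999, by = 50)))
  wt <- mk_methylome(pos, meth = 16, total = 20, id = "wt")
  mut_meth <- unlist(lapply(seq_len(n), function(i) rep(16L - i, 20)))
  mut <- mk_methylome(pos, meth = mut_meth, total = 20, id = "mut")
  # ChIP gain increasing in the same DMR order
  mk_crs <- function(counts) {
    rr <- lapply(seq_len(n), function(i) {
      s <- starts[i] + seq(0, length.out = counts[i], by = 7)
      mk_reads("Chr1", s, s + 50)
    })
    crs <- collapse_duplicates(do.call(c, rr), cap = 1)
    crs$total_mapped <- 1e6
    crs
  }
  chip_wt <- mk_crs(rep(5L, n))
  chip_mut <- mk_crs(5L + seq_len(n) * 3L)
  res <- weighted_change_correlation(dmrs, chip_wt, chip_mut, list(wt), mut)
  expect_equal(res$rho, 1)
  # anti-monotone ChIP change
  chip_mut_rev <- mk_crs(5L + rev(seq_len(n)) * 3L)
  res2 <- weighted_change_correlation(dmrs, chip_wt, chip_mut_rev,
                                      list(wt), mut)
  expect_equal(res2$rho, -1)
  expect_error(weighted_change_correlation(dmrs[1:2], chip_wt, chip_mut,
                                           list(wt), mut), "3 DMRs")
})
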