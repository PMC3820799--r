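# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

mk_methylome <- function(pos, meth, total, chrom = "Chr1", strand = "+",
                         context = "CHH", id = "lib") {
  n <- length(pos)
  methylome_table(data.table::data.table(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    strand = rep_len(strand, n), context = rep_len(context, n),
    meth = as.integer(rep_len(meth, n)),
    total = as.integer(rep_len(total, n))), id)
}

mk_reads <- function(chrom, start, end, strand = "+", unique = TRUE,
                     mult = 1L) {
  n <- length(start)
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(chrom, n),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = rep_len(strand, n))
  gr$is_unique <- rep_len(unique, n)
  gr$multiplicity <- as.integer(rep_len(mult, n))
  gr
}

mk_intervals <- function(chrom, start, end, strand = "*") {
  n <- length(start)
  GenomicRanges::GRanges(
    seqnames = rep_len(chrom, n),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = rep_len(strand, n))
}

mk_genes <- function(chrom, start, end, strand = "+",
                     ids = sprintf("g%03d", seq_along(start))) {
  gr <- mk_intervals(chrom, start, end, strand)
  gr$gene_id <- ids
  plus <- as.character(GenomicRanges::strand(gr)) != "-"
  gr$tss <- ifelse(plus, as.integer(start), as.integer(end) - 1L)
  gr
}

# smoothed track as site_statistics() expects it
mk_track <- function(pos, mu_wt, mu_mut, sigma, wt_mean_p = mu_wt,
                     mut_p = mu_mut, chrom = "Chr1", sigma_floor = NULL) {
  n <- length(pos)
  dt <- data.table::data.table(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    mu_wt = rep_len(mu_wt, n), mu_mut = rep_len(mu_mut, n),
    sigma = rep_len(sigma, n),
    wt_mean_p = rep_len(wt_mean_p, n), mut_p = rep_len(mut_p, n))
  if (is.null(sigma_floor))
    sigma_floor <- max(stats::median(dt$sigma), 1e-8)
  data.table::setattr(dt, "sigma_floor", sigma_floor)
  dt
}

# enumeration oracle for the two-sided Mann-Whitney exact p-value
# (no-ties case); follows the standard two-sided convention
# p = min(1, 2 * tail beyond the observed U on the shorter side of n1*n2/2)
mwu_enum_p <- function(x, y) {
  comb <- c(x, y)
  n1 <- length(x)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">"))
  u_obs <- u_of(x, y)
  sets <- utils::combn(seq_along(comb), n1)
  us <- apply(sets, 2, function(ix) u_of(comb[ix], comb[-ix]))
  if (u_obs > n1 * (length(comb) - n1) / 2) {
    p <- 2 * mean(us >= u_obs)
  } else {
    p <- 2 * mean(us <= u_obs)
  }
  min(p, 1)
}

# direct Welch formulas
welch_oracle <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(statistic = t, df = df, p_value = p)
}

# tiny reference simulation shared by caller tests (kept small for speed)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, n_chrom = 1, chrom_length = 15e4,
                        n_dmrs = 5, dmr_width = 800, min_chh_sites = 30,
                        gene_density = 0.25)
      g <- simulate_genome(cfg)
      tr <- simulate_truth(g, cfg)
      tr <- simulate_annotation(g, cfg, tr)
      sim <- simulate_methylomes(g, cfg, tr)
      cache <<- list(cfg = cfg, g = g, tr = tr, sim = sim)
    }
    cache
  }
})
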