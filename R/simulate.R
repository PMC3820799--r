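# Seeded synthetic-data generator: genome, replicate methylomes with
# implanted CHH-hypomethylated regions, gene annotation, and ChIP / sRNA /
# mRNA read sets, plus a truth record for recovery tests.
#
# Every generator derives its RNG stream from config$seed plus a fixed,
# documented stage offset, so each stage is individually reproducible and
# independent of call order.

SEED_OFFSETS <- c(genome = 0L, truth = 2L, annotation = 3L, methylomes = 1L,
                  chip_wt = 10L, chip_mut = 11L, srna_wt = 12L,
                  srna_mut = 13L, mrna = 20L)

#' Build a simulation configuration
#'
#' Defaults describe the reference scenario used throughout the test suite:
#' a 2-Mb genome (two 1-Mb chromosomes), four wild-type replicate methylomes
#' plus one mutant, mean per-site coverage 8, and 50 implanted 1-kb regions
#' in which the mutant's regional CHH methylation is reduced by 0.3 from a
#' wild-type level of 0.4 (an RdDM-target-like level; genome background CG /
#' CHG / CHH levels emulate a methylated, transposon-dense compartment).
#'
#' @param seed Integer seed; all stage seeds are derived from it.
#' @param n_chrom,chrom_length Number and length (bp) of chromosomes.
#' @param n_wt_replicates Wild-type methylome replicates (default 4).
#' @param mutant_specs List of mutant descriptions, each a list with
#'   `label`, `dmr_effect` (methylation fraction lost in implants),
#'   `h3k4_gain` (fold ChIP rate gain inside implants), `srna_depletion`
#'   (fraction of implant sRNA cluster rate lost).
#' @param n_dmrs,dmr_width Number and width (bp) of implanted regions.
#' @param min_chh_sites Minimum CHH sites an implanted region must contain.
#' @param coverage_mean Mean per-site read coverage (Poisson).
#' @param background_chh_level,background_chg_level,background_cg_level
#'   Wild-type methylation fractions by context.
#' @param beta_precision Concentration of the per-site Beta drawing
#'   methylation propensities around regional means (site-level
#'   overdispersion; counts are beta-binomial).
#' @param gene_density Genes per kilobase.
#' @param gene_width_range Min/max gene width (bp).
#' @param near_gene_fraction Fraction of implants with a gene placed within
#'   `near_gene_max_offset` bp of an implant edge.
#' @param near_gene_max_offset Maximum implant-to-gene gap (bp) for the
#'   near-gene implants.
#' @param read_length ChIP/mRNA read length (nt).
#' @param chip_reads,srna_reads,mrna_reads Read rows generated per library.
#' @param chip_tss_fold Rate fold in the first `chip_tss_zone` bp downstream
#'   of each TSS versus background (5' H3K4 enrichment of genes).
#' @param chip_tss_zone 5' enrichment zone width (bp).
#' @param chip_dup_rate Poisson rate of extra identical ChIP read copies.
#' @param srna_dmr_fraction Fraction of wild-type sRNA cluster mass at
#'   implanted regions (rest in background clusters).
#' @param srna_cluster_width,srna_n_background_clusters Background sRNA
#'   cluster geometry.
#' @param srna_dup_mean Mean sRNA read multiplicity (1 + geometric), a
#'   heavy-tailed duplication law so the 100-read cap is exercised.
#' @param srna_nonunique_fraction Fraction of sRNA reads flagged
#'   multi-mapping.
#' @param srna_len_probs Probabilities for read lengths 18..28 nt
#'   (24-nt mode).
#' @param mrna_gene_shape Gamma shape for per-gene expression rates
#'   (identical between genotypes).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 1e6,
                       n_wt_replicates = 4L,
                       mutant_specs = list(list(label = "mut1",
                                                dmr_effect = 0.3,
                                                h3k4_gain = 3,
                                                srna_depletion = 0.9)),
                       n_dmrs = 50L,
                       dmr_width = 1000L,
                       min_chh_sites = 30L,
                       coverage_mean = 8,
                       background_chh_level = 0.4,
                       background_chg_level = 0.6,
                       background_cg_level = 0.85,
                       beta_precision = 30,
                       gene_density = 0.25,
                       gene_width_range = c(1000L, 3000L),
                       near_gene_fraction = 0.7,
                       near_gene_max_offset = 300L,
                       read_length = 50L,
                       chip_reads = 2e5,
                       srna_reads = 1e5,
                       mrna_reads = 2e5,
                       chip_tss_fold = 5,
                       chip_tss_zone = 500L,
                       chip_dup_rate = 0.05,
                       srna_dmr_fraction = 0.7,
                       srna_cluster_width = 500L,
                       srna_n_background_clusters = NULL,
                       srna_dup_mean = 20,
                       srna_nonunique_fraction = 0.2,
                       srna_len_probs = c(2, 3, 4, 6, 8, 12, 40, 10, 6, 4, 2),
                       mrna_gene_shape = 2) {
  cfg <- as.list(environment())
  if (is.null(cfg$srna_n_background_clusters))
    cfg$srna_n_background_clusters <- max(10L, as.integer(n_dmrs))
  if (cfg$chrom_length < 1000) stop("chrom_length must be >= 1 kb")
  if (cfg$n_wt_replicates < 1) stop("need at least one wild-type replicate")
  if (!length(cfg$mutant_specs)) stop("mutant_specs must be non-empty")
  labs <- vapply(cfg$mutant_specs, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("duplicate mutant labels")
  for (ms in cfg$mutant_specs) {
    if (ms$dmr_effect < 0 || ms$dmr_effect > 1)
      stop("dmr_effect must be in [0, 1]")
    if (ms$srna_depletion < 0 || ms$srna_depletion > 1)
      stop("srna_depletion must be in [0, 1]")
    if (ms$h3k4_gain < 1) stop("h3k4_gain must be >= 1")
  }
  lv <- c(cfg$background_chh_level, cfg$background_chg_level,
          cfg$background_cg_level)
  if (any(lv < 0 | lv > 1)) stop("background levels must be in [0, 1]")
  if (length(cfg$srna_len_probs) != 11)
    stop("srna_len_probs must cover lengths 18..28")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

stage_seed <- function(config, stage, replicate = 1L) {
  config$seed + SEED_OFFSETS[[stage]] + 100L * (as.integer(replicate) - 1L)
}

#' Simulate a random genome and its cytosine catalogue
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [Biostrings::DNAStringSet]), `catalogue`
#'   (per-cytosine context table from [cytosine_catalogue()]) and `seqinfo`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "genome"))
  L <- as.integer(config$chrom_length)
  seqs <- vapply(seq_len(config$n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- paste0("Chr", seq_len(config$n_chrom))
  genome <- Biostrings::DNAStringSet(seqs)
  list(genome = genome,
       catalogue = cytosine_catalogue(genome),
       seqinfo = genome_seqinfo(genome))
}

#' Place implanted hypomethylated regions and sRNA background clusters
#'
#' Implants are non-overlapping, uniformly placed intervals of
#' `dmr_width` bp each containing at least `min_chh_sites` CHH cytosines.
#' Background sRNA clusters are placed uniformly, avoiding the implants, so
#' that fully depleted mutants carry no sRNA reads inside implants.
#'
#' @param genome_obj Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @return A `SyntheticTruth` list: `implants` (`GRanges` with `implant_id`,
#'   `n_chh`), `effects` (per-mutant data.frame of `dmr_effect`,
#'   `h3k4_gain`, `srna_depletion`), `srna_bg_clusters` (`GRanges`).
#' @export
simulate_truth <- function(genome_obj, config) {
  set.seed(stage_seed(config, "truth"))
  si <- genome_obj$seqinfo
  chroms <- names(genome_obj$genome)
  lens <- stats::setNames(IRanges::width(genome_obj$genome), chroms)
  chh <- genome_obj$catalogue[context == "CHH"]
  chh_pos <- split(chh$pos, chh$chrom)
  w <- as.integer(config$dmr_width)
  n <- as.integer(config$n_dmrs)

  placed <- data.table::data.table(chrom = character(), start = integer(),
                                   end = integer())
  tries <- 0L
  while (nrow(placed) < n && tries < 200L * n) {
    tries <- tries + 1L
    cn <- sample(chroms, 1L, prob = lens)
    s <- sample.int(lens[[cn]] - w, 1L) - 1L
    e <- s + w
    pp <- chh_pos[[cn]]
    nchh <- if (is.null(pp)) 0L else
      findInterval(e - 0.5, pp) - findInterval(s - 0.5, pp)
    if (nchh < config$min_chh_sites) next
    if (nrow(placed[chrom == cn & start < e & end > s])) next
    placed <- rbind(placed, data.table::data.table(
      chrom = cn, start = s, end = e, n_chh = nchh), fill = TRUE)
  }
  if (nrow(placed) < n)
    stop("could only place ", nrow(placed), " of ", n,
         " non-overlapping implants with >= ", config$min_chh_sites,
         " CHH sites")
  data.table::setorder(placed, chrom, start)
  implants <- gr0(placed$chrom, placed$start, placed$end, seqinfo = si)
  implants$implant_id <- sprintf("dmr%04d", seq_len(n))
  implants$n_chh <- placed$n_chh

  # background sRNA clusters avoid implants
  bw <- as.integer(config$srna_cluster_width)
  nb <- as.integer(config$srna_n_background_clusters)
  bg <- data.table::data.table(chrom = character(), start = integer(),
                               end = integer())
  tries <- 0L
  while (nrow(bg) < nb && tries < 200L * nb) {
    tries <- tries + 1L
    cn <- sample(chroms, 1L, prob = lens)
    s <- sample.int(lens[[cn]] - bw, 1L) - 1L
    e <- s + bw
    if (nrow(placed[chrom == cn & start < e & end > s])) next
    if (nrow(bg[chrom == cn & start < e & end > s])) next
    bg <- rbind(bg, data.table::data.table(chrom = cn, start = s, end = e))
  }
  if (nrow(bg) < nb) stop("could not place sRNA background clusters")
  data.table::setorder(bg, chrom, start)

  effects <- data.table::rbindlist(lapply(config$mutant_specs, function(ms)
    data.table::data.table(label = ms$label, dmr_effect = ms$dmr_effect,
                           h3k4_gain = ms$h3k4_gain,
                           srna_depletion = ms$srna_depletion)))

  list(implants = implants,
       effects = effects,
       srna_bg_clusters = gr0(bg$chrom, bg$start, bg$end, seqinfo = si))
}

#' Simulate gene annotation and per-gene expression rates
#'
#' Places non-overlapping gene models; a fraction `near_gene_fraction` of
#' implants receives a gene within `near_gene_max_offset` bp of one of its
#' edges (emulating hypomethylated regions lying close to genes), remaining
#' genes are uniform. Per-gene mRNA rates (Gamma distributed, mean 1) are
#' drawn here once so both genotypes share them.
#'
#' @param genome_obj Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @return `truth` augmented with `genes` (`GRanges` with `gene_id`, `tss`)
#'   and `gene_rates`.
#' @export
simulate_annotation <- function(genome_obj, config, truth) {
  set.seed(stage_seed(config, "annotation"))
  chroms <- names(genome_obj$genome)
  lens <- stats::setNames(IRanges::width(genome_obj$genome), chroms)
  total_kb <- sum(lens) / 1000
  n_genes <- round(config$gene_density * total_kb)
  if (n_genes < 1) stop("gene_density too low: zero genes requested")
  wr <- config$gene_width_range

  genes <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character())
  add_gene <- function(cn, s, e, strand) {
    if (s < 0 || e > lens[[cn]] || e <= s) return(FALSE)
    if (nrow(genes[chrom == cn & start < e & end > s])) return(FALSE)
    genes <<- rbind(genes, data.table::data.table(
      chrom = cn, start = as.integer(s), end = as.integer(e),
      strand = strand))
    TRUE
  }

  impl <- truth$implants
  k <- round(config$near_gene_fraction * length(impl))
  near_idx <- if (k > 0) sort(sample(seq_along(impl), k)) else integer(0)
  for (i in near_idx) {
    cn <- as.character(GenomicRanges::seqnames(impl[i]))
    gw <- sample(wr[1]:wr[2], 1L)
    ok <- FALSE
    for (side in sample(c("right", "left"))) {
      off <- sample.int(config$near_gene_max_offset + 1L, 1L) - 1L
      if (side == "right") {
        s <- end0(impl[i]) + off
        ok <- add_gene(cn, s, s + gw, sample(c("+", "-"), 1L))
      } else {
        e <- start0(impl[i]) - off
        ok <- add_gene(cn, e - gw, e, sample(c("+", "-"), 1L))
      }
      if (ok) break
    }
    # implants deep in gene-free space may fail both sides; tolerated,
    # the near-gene fraction is then approximate
  }
  tries <- 0L
  while (nrow(genes) < n_genes && tries < 300L * n_genes) {
    tries <- tries + 1L
    cn <- sample(chroms, 1L, prob = lens)
    gw <- sample(wr[1]:wr[2], 1L)
    if (gw >= lens[[cn]]) next
    s <- sample.int(lens[[cn]] - gw, 1L) - 1L
    add_gene(cn, s, s + gw, sample(c("+", "-"), 1L))
  }
  if (nrow(genes) < n_genes)
    stop("gene_density too high: placed ", nrow(genes), " of ", n_genes,
         " genes without overlap")
  data.table::setorder(genes, chrom, start)
  gg <- gr0(genes$chrom, genes$start, genes$end, genes$strand,
            seqinfo = genome_obj$seqinfo)
  gg$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
  gg$tss <- gene_tss(gg)

  truth$genes <- gg
  truth$gene_rates <- stats::setNames(
    rgamma(length(gg), shape = config$mrna_gene_shape,
           rate = config$mrna_gene_shape), gg$gene_id)
  truth
}

#' Simulate wild-type replicate and mutant methylomes
#'
#' Per-site coverage is Poisson(`coverage_mean`); the methylated count is
#' Binomial(coverage, p) with p drawn per site and library from a Beta
#' distribution with mean equal to the regional level and concentration
#' `beta_precision` (beta-binomial overdispersion). Wild-type replicates
#' share regional means; inside an implant a mutant's CHH regional mean is
#' the wild-type mean minus that mutant's `dmr_effect`. CG/CHG levels are
#' unchanged in mutants.
#'
#' @param genome_obj Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @param truth Optional output of [simulate_truth()]; created when absent.
#' @return List with `wt` (list of `MethylomeTable`), `mutants` (named list
#'   of `MethylomeTable`) and `truth`.
#' @export
simulate_methylomes <- function(genome_obj, config, truth = NULL) {
  if (is.null(truth)) truth <- simulate_truth(genome_obj, config)
  set.seed(stage_seed(config, "methylomes"))
  cat <- data.table::copy(genome_obj$catalogue)
  base_mean <- c(CG = config$background_cg_level,
                 CHG = config$background_chg_level,
                 CHH = config$background_chh_level)
  cat[, wt_mean := base_mean[context]]

  # flag CHH sites inside implants
  impl <- truth$implants
  cat[, in_implant := FALSE]
  if (length(impl)) {
    idt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(impl)),
      start = start0(impl), end = end0(impl))
    for (i in seq_len(nrow(idt))) {
      cat[chrom == idt$chrom[i] & pos >= idt$start[i] & pos < idt$end[i] &
            context == "CHH", in_implant := TRUE]
    }
  }

  nu <- config$beta_precision
  draw_library <- function(mean_vec, library_id) {
    n <- nrow(cat)
    covv <- rpois(n, config$coverage_mean)
    m <- pmin(pmax(mean_vec, 1e-3), 1 - 1e-3)
    p <- rbeta(n, m * nu, (1 - m) * nu)
    meth <- rbinom(n, covv, p)
    methylome_table(data.table::data.table(
      chrom = cat$chrom, pos = cat$pos, strand = cat$strand,
      context = cat$context, meth = meth, total = covv), library_id)
  }

  wt <- lapply(seq_len(config$n_wt_replicates), function(r)
    draw_library(cat$wt_mean, paste0("WT_rep", r)))
  names(wt) <- vapply(wt, attr, "", "library_id")

  mutants <- lapply(config$mutant_specs, function(ms) {
    mv <- cat$wt_mean
    mv[cat$in_implant] <- pmax(mv[cat$in_implant] - ms$dmr_effect, 0)
    draw_library(mv, ms$label)
  })
  names(mutants) <- vapply(config$mutant_specs, `[[`, "", "label")

  cat[, c("wt_mean", "in_implant") := NULL]
  list(wt = wt, mutants = mutants, truth = truth)
}

# sample n read start positions uniformly within segments (GRanges),
# leaving room for read length; returns GRanges with given strand policy
sample_reads_in <- function(segments, n, len, strand = NULL, seqinfo = NULL) {
  if (n == 0 || length(segments) == 0) {
    return(GenomicRanges::GRanges(seqinfo = seqinfo))
  }
  avail <- pmax(IRanges::width(segments) - len, 0L)
  keep <- avail > 0
  segments <- segments[keep]; avail <- avail[keep]
  if (!length(segments)) return(GenomicRanges::GRanges(seqinfo = seqinfo))
  seg <- sample.int(length(segments), n, replace = TRUE, prob = avail)
  off <- floor(runif(n) * avail[seg])
  s0 <- start0(segments)[seg] + off
  str <- if (is.null(strand)) sample(c("+", "-"), n, replace = TRUE)
         else as.character(GenomicRanges::strand(segments))[seg]
  gr0(as.character(GenomicRanges::seqnames(segments))[seg],
      s0, s0 + len, str, seqinfo = seqinfo)
}

#' Simulate an aligned-read set for one assay
#'
#' Assays: `chip_wt`/`chip_mut` (50-nt reads from a background + 5'-gene
#' enrichment mixture, the mutant adding `h3k4_gain`-fold rate inside
#' implants), `srna_wt`/`srna_mut` (18-28-nt reads, 24-nt mode, confined to
#' implant and background clusters, geometric duplication, a fraction
#' flagged multi-mapping; the mutant thins implant cluster rate by
#' `srna_depletion`), `mrna` (reads inside gene bodies at per-gene rates
#' identical between genotypes; call twice with different `replicate` for
#' the two genotype libraries).
#'
#' @param genome_obj Output of [simulate_genome()].
#' @param truth Output of [simulate_annotation()] (genes required for
#'   chip/mrna).
#' @param assay One of `"chip_wt"`, `"chip_mut"`, `"srna_wt"`,
#'   `"srna_mut"`, `"mrna"`.
#' @param config A [sim_config()].
#' @param mutant Label of the mutant whose effects apply (default: first).
#' @param replicate Integer entering the seed so repeated libraries differ.
#' @return `GRanges` read set with `is_unique` and `multiplicity` columns.
#' @export
simulate_reads <- function(genome_obj, truth, assay, config,
                           mutant = NULL, replicate = 1L) {
  assays <- c("chip_wt", "chip_mut", "srna_wt", "srna_mut", "mrna")
  if (!assay %in% assays)
    stop("unknown assay label: ", assay, " (expected one of ",
         paste(assays, collapse = ", "), ")")
  set.seed(stage_seed(config, assay, replicate))
  si <- genome_obj$seqinfo
  chroms <- names(genome_obj$genome)
  lens <- IRanges::width(genome_obj$genome)
  whole <- gr0(chroms, rep(0L, length(chroms)), lens, seqinfo = si)
  eff <- if (is.null(mutant)) truth$effects[1]
         else truth$effects[truth$effects$label == mutant]
  if (!nrow(eff)) stop("unknown mutant label: ", mutant)

  if (startsWith(assay, "chip")) {
    if (is.null(truth$genes)) stop("truth lacks gene annotation")
    len <- config$read_length
    n <- as.integer(config$chip_reads)
    tsszone <- five_prime_zone(truth$genes, config$chip_tss_zone)
    comps <- list(whole, tsszone)
    wts <- c(sum(lens), sum(IRanges::width(tsszone)) * (config$chip_tss_fold - 1))
    if (assay == "chip_mut" && eff$h3k4_gain > 1) {
      comps <- c(comps, list(truth$implants))
      wts <- c(wts, sum(IRanges::width(truth$implants)) * (eff$h3k4_gain - 1))
    }
    comp <- sample.int(length(comps), n, replace = TRUE, prob = wts)
    reads <- do.call(c, lapply(seq_along(comps), function(i)
      sample_reads_in(comps[[i]], sum(comp == i), len, seqinfo = si)))
    reads$is_unique <- TRUE
    reads$multiplicity <- 1L + rpois(length(reads), config$chip_dup_rate)
    return(sort(reads))
  }

  if (startsWith(assay, "srna")) {
    n <- as.integer(config$srna_reads)
    f <- config$srna_dmr_fraction
    w_impl <- f
    w_bg <- 1 - f
    if (assay == "srna_mut") {
      w_impl <- w_impl * (1 - eff$srna_depletion)
      n <- round(n * (w_impl + w_bg) / 1)
    }
    n_impl <- rbinom(1, n, if (w_impl + w_bg > 0) w_impl / (w_impl + w_bg) else 0)
    n_bg <- n - n_impl
    lengths <- sample(18:28, n, replace = TRUE,
                      prob = config$srna_len_probs)
    mk <- function(segments, nn, lens_nt) {
      if (nn == 0) return(GenomicRanges::GRanges(seqinfo = si))
      do.call(c, unname(lapply(split(seq_len(nn), lens_nt), function(ii) {
        sample_reads_in(segments, length(ii), lens_nt[ii[1]], seqinfo = si)
      })))
    }
    reads <- c(mk(truth$implants, n_impl, lengths[seq_len(n_impl)]),
               mk(truth$srna_bg_clusters, n_bg,
                  lengths[n_impl + seq_len(n_bg)]))
    nr <- length(reads)
    reads$is_unique <- runif(nr) >= config$srna_nonunique_fraction
    reads$multiplicity <- 1L + rgeom(nr, 1 / config$srna_dup_mean)
    return(sort(reads))
  }

  # mrna
  if (is.null(truth$genes)) stop("truth lacks gene annotation")
  len <- config$read_length
  n <- as.integer(config$mrna_reads)
  rates <- truth$gene_rates[truth$genes$gene_id]
  wts <- rates * pmax(IRanges::width(truth$genes) - len, 0)
  gidx <- sample.int(length(truth$genes), n, replace = TRUE, prob = wts)
  gsel <- truth$genes[gidx]
  off <- floor(runif(n) * (IRanges::width(gsel) - len))
  s0 <- start0(gsel) + off
  reads <- gr0(as.character(GenomicRanges::seqnames(gsel)), s0, s0 + len,
               as.character(GenomicRanges::strand(gsel)), seqinfo = si)
  reads$is_unique <- TRUE
  reads$multiplicity <- 1L
  sort(reads)
}

# strand-oriented [tss, tss + zone) interval per gene, clipped
five_prime_zone <- function(genes, zone) {
  tss <- genes$tss
  plus <- as.character(GenomicRanges::strand(genes)) != "-"
  s <- ifelse(plus, tss, tss - zone + 1L)
  e <- ifelse(plus, tss + zone, tss + 1L)
  s <- pmax(s, 0L)
  gr <- gr0(as.character(GenomicRanges::seqnames(genes)), s, e,
            as.character(GenomicRanges::strand(genes)),
            seqinfo = GenomeInfoDb_seqinfo(genes))
  IRanges::trim(gr)
}

GenomeInfoDb_seqinfo <- function(gr) {
  tryCatch(GenomeInfoDb::seqinfo(gr), error = function(e) NULL)
}

#' Write the synthetic truth record as JSON
#' @param truth Truth list from [simulate_annotation()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  gr_df <- function(gr) data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0(gr), end = end0(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    S4Vectors::mcols(gr), check.names = FALSE)
  obj <- list(implants = gr_df(truth$implants),
              effects = as.data.frame(truth$effects),
              srna_bg_clusters = gr_df(truth$srna_bg_clusters))
  if (!is.null(truth$genes)) {
    obj$genes <- gr_df(truth$genes)
    obj$gene_rates <- as.list(truth$gene_rates)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
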