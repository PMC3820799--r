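# End-to-end orchestration: simulate -> call DMRs -> region comparison ->
# signal quantification -> expression, with a reproducibility manifest.

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a genome, methylomes, annotation and read sets from `config`,
#' writes them to `outdir`, calls CHH hypomethylation DMRs for every mutant,
#' and aggregates: recovery against the implanted truth (sensitivity and
#' false-discovery proportion by >= 1 bp overlap), Venn classes across
#' mutant DMR sets (or called-vs-truth for a single mutant), nearest-gene
#' distances, H3K4 window-density and 24-nt sRNA depletion tests at truth
#' regions, and the promoter-gene expression null check. A manifest records
#' the seed, all thresholds, and MD5 checksums of every written file;
#' re-running with the same config reproduces identical outputs.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created).
#' @param params DMR-calling parameters from [dmr_params()].
#' @return Invisibly, a list with `manifest` and `report` (also written as
#'   JSON under `outdir`).
#' @export
run_full_pipeline <- function(config, outdir, params = dmr_params()) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$mutant_specs))
    stop("validation failure: no mutant libraries configured")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(p) { paths[[length(paths) + 1]] <<- p; p }
  stage_log <- character(0)
  log_stage <- function(msg) stage_log[[length(stage_log) + 1]] <<- msg

  # --- simulate -------------------------------------------------------------
  g <- simulate_genome(config)
  Biostrings::writeXStringSet(g$genome, put(file.path(outdir, "genome.fa")))
  truth <- simulate_truth(g, config)
  truth <- simulate_annotation(g, config, truth)
  write_truth_json(truth, put(file.path(outdir, "truth.json")))
  write_gff_genes(truth$genes, put(file.path(outdir, "genes.gff3")))
  sim <- simulate_methylomes(g, config, truth)
  for (nm in names(sim$wt))
    write_methylome_tsv(sim$wt[[nm]],
                        put(file.path(outdir, paste0(nm, ".meth.tsv"))))
  for (nm in names(sim$mutants))
    write_methylome_tsv(sim$mutants[[nm]],
                        put(file.path(outdir, paste0(nm, ".meth.tsv"))))
  reads <- list(
    chip_wt = simulate_reads(g, truth, "chip_wt", config),
    chip_mut = simulate_reads(g, truth, "chip_mut", config),
    srna_wt = simulate_reads(g, truth, "srna_wt", config),
    srna_mut = simulate_reads(g, truth, "srna_mut", config),
    mrna_wt = simulate_reads(g, truth, "mrna", config, replicate = 1),
    mrna_mut = simulate_reads(g, truth, "mrna", config, replicate = 2))
  for (nm in names(reads))
    write_bed(reads[[nm]], put(file.path(outdir, paste0(nm, ".bed"))))
  log_stage("simulate: ok")

  # --- DMR calling ----------------------------------------------------------
  dmr_sets <- list()
  for (nm in names(sim$mutants)) {
    dmrs <- call_chh_dmrs(sim$wt, sim$mutants[[nm]], params,
                          seqinfo = g$seqinfo)
    dmr_sets[[nm]] <- dmrs
    write_bed(dmrs, put(file.path(outdir, paste0("dmrs_", nm, ".bed"))))
    stats_dt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(dmrs)),
      start = start0(dmrs), end = end0(dmrs),
      n_chh = dmrs$n_chh, mean_diff = dmrs$mean_diff, area = dmrs$area,
      direction = dmrs$direction)
    data.table::fwrite(stats_dt,
                       put(file.path(outdir, paste0("dmrs_", nm, ".tsv"))),
                       sep = "\t")
    audit <- audit_dmrs(dmrs, sim$wt, sim$mutants[[nm]], params)
    if (nrow(audit) && !all(audit$pass))
      stop("stage dmr_caller: audit failed for dmrs_", nm, ".bed")
  }
  log_stage("dmr_caller: ok")

  # --- report ---------------------------------------------------------------
  first <- names(dmr_sets)[1]
  dmrs1 <- dmr_sets[[first]]
  report <- list(seed = config$seed,
                 dmr_counts = lapply(dmr_sets, length))
  report$recovery <- lapply(dmr_sets, function(d)
    dmr_recovery(d, truth$implants))
  venn_in <- if (length(dmr_sets) >= 2) dmr_sets[1:min(3, length(dmr_sets))]
             else c(dmr_sets, list(truth = truth$implants))
  nonempty <- vapply(venn_in, length, 0L) > 0
  if (sum(nonempty) >= 2) {
    vc <- venn_counts(venn_in[nonempty])
    report$venn <- as.list(vc)
  }
  if (length(dmrs1)) {
    d <- distance_to_nearest_gene(dmrs1, truth$genes)
    report$distance_to_gene <- list(n = sum(!is.na(d)),
                                    mean = mean(d, na.rm = TRUE),
                                    median = stats::median(d, na.rm = TRUE))
  }

  chip_wt <- collapse_duplicates(reads$chip_wt, cap = 1, assay = "chip")
  chip_mut <- collapse_duplicates(reads$chip_mut, cap = 1, assay = "chip")
  sl <- stats::setNames(IRanges::width(g$genome), names(g$genome))
  w_wt <- dmr_window_density(truth$implants, chip_wt, 500, sl)
  w_mut <- dmr_window_density(truth$implants, chip_mut, 500, sl)
  report$h3k4_window_test <- mann_whitney_u(w_mut, w_wt)

  srna_wt <- collapse_duplicates(
    select_srna(reads$srna_wt, size_class = 24), cap = 100, assay = "srna")
  srna_wt$total_mapped <- sum(collapse_duplicates(
    select_srna(reads$srna_wt, 18, 28), 100)$reads$multiplicity)
  srna_mut <- collapse_duplicates(
    select_srna(reads$srna_mut, size_class = 24), cap = 100, assay = "srna")
  srna_mut$total_mapped <- sum(collapse_duplicates(
    select_srna(reads$srna_mut, 18, 28), 100)$reads$multiplicity)
  s_wt <- dmr_window_density(truth$implants, srna_wt, 500, sl)
  s_mut <- dmr_window_density(truth$implants, srna_mut, 500, sl)
  report$srna_depletion_test <- mann_whitney_u(s_mut, s_wt)

  mrna_wt <- collapse_duplicates(reads$mrna_wt, cap = 1, assay = "mrna")
  mrna_mut <- collapse_duplicates(reads$mrna_mut, cap = 1, assay = "mrna")
  pg <- genes_with_dmr_promoters(truth$genes, truth$implants)
  if (length(pg)) {
    lr <- log2_expression_ratio(count_gene_reads(pg, mrna_mut),
                                count_gene_reads(pg, mrna_wt),
                                mrna_mut$total_mapped, mrna_wt$total_mapped)
    report$expression_null <- list(n_genes = length(pg),
                                   median_log2_ratio = stats::median(lr))
  }
  log_stage("integrate: ok")

  report_path <- put(file.path(outdir, "report.json"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)

  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "mutant_specs")],
    mutant_specs = config$mutant_specs,
    dmr_params = params,
    stages = stage_log,
    files = {
      f <- sort(unlist(paths))
      as.list(stats::setNames(as.character(tools::md5sum(f)), basename(f)))
    })
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(manifest = manifest, report = report))
}

#' Sensitivity and false-discovery proportion against implanted truth
#'
#' A truth region is recovered when any called DMR overlaps it by >= 1 bp;
#' a called DMR is a false discovery when it overlaps no truth region.
#'
#' @param called,truth_dmrs `GRanges`.
#' @return List: `sensitivity`, `fdp`, `n_called`, `n_truth`.
#' @export
dmr_recovery <- function(called, truth_dmrs) {
  hit_truth <- IRanges::overlapsAny(truth_dmrs, called, minoverlap = 1L)
  fp <- !IRanges::overlapsAny(called, truth_dmrs, minoverlap = 1L)
  list(sensitivity = if (length(truth_dmrs)) mean(hit_truth) else NA_real_,
       fdp = if (length(called)) mean(fp) else 0,
       n_called = length(called),
       n_truth = length(truth_dmrs))
}
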