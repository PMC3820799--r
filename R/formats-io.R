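# File formats, coordinate conventions and core containers.
#
# Internal convention: 0-based half-open coordinates everywhere. 1-based
# coordinates appear only at the TSV/GFF3 boundary (and inside GRanges,
# which are 1-based closed by construction; converters below are the only
# place that translation happens).

VALID_CONTEXTS <- c("CG", "CHG", "CHH")

# ---- genome / cytosine context ---------------------------------------------

#' Classify the trinucleotide context of a cytosine
#'
#' Determines CG / CHG / CHH context from the two bases immediately
#' downstream of a cytosine on its own strand (H = A, C or T). On the minus
#' strand, downstream means leftward on the reference and bases are
#' complemented.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector) of
#'   chromosome sequences.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s) of the cytosine on the reference.
#' @param strand `"+"` or `"-"`, recycled.
#' @return Character vector with values `"CG"`, `"CHG"`, `"CHH"`, or
#'   `"incomplete"` when fewer than two downstream bases exist (such sites
#'   are excluded from all downstream analyses).
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  genome <- as_genome_chars(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  out <- character(n)
  for (cn in unique(chrom)) {
    if (!cn %in% names(genome)) stop("unknown chromosome: ", cn)
    v <- genome[[cn]]
    idx <- which(chrom == cn)
    out[idx] <- classify_context_chrom(v, pos[idx], strand[idx])
  }
  out
}

# genome as list of per-chromosome character vectors of single bases
as_genome_chars <- function(genome) {
  if (is.list(genome) && all(vapply(genome, is.character, TRUE)) &&
      !is.null(names(genome)) && all(lengths(genome) > 1)) {
    return(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- genome
  } else {
    stop("genome must be a DNAStringSet or named character vector")
  }
  if (is.null(names(seqs))) stop("genome sequences must be named")
  lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

classify_context_chrom <- function(v, pos, strand) {
  L <- length(v)
  if (any(pos < 0L | pos >= L)) stop("position outside chromosome")
  base <- v[pos + 1L]
  plus <- strand == "+"
  ok <- ifelse(plus, base == "C", base == "G")
  if (!all(ok)) stop("not a cytosine at position ",
                     pos[which(!ok)[1]], " strand ", strand[which(!ok)[1]])
  out <- rep("incomplete", length(pos))
  # plus strand: downstream bases at pos+1, pos+2 (0-based)
  ip <- which(plus & pos + 2L <= L - 1L)
  if (length(ip)) {
    b1 <- v[pos[ip] + 2L]; b2 <- v[pos[ip] + 3L]
    out[ip] <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
  }
  # minus strand: downstream bases at pos-1, pos-2, complemented
  im <- which(!plus & pos - 2L >= 0L)
  if (length(im)) {
    b1 <- unname(COMPLEMENT[v[pos[im]]])
    b2 <- unname(COMPLEMENT[v[pos[im] - 1L]])
    out[im] <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
  }
  out
}

#' Catalogue every cytosine in a genome with its context
#'
#' Scans both strands of every chromosome and returns one row per cytosine.
#' Sites with fewer than two downstream bases (chromosome ends) are excluded.
#'
#' @inheritParams classify_context
#' @return A `data.table` with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, sorted by `(chrom, pos, strand)`.
#' @export
cytosine_catalogue <- function(genome) {
  genome <- as_genome_chars(genome)
  parts <- lapply(names(genome), function(cn) {
    v <- genome[[cn]]
    pp <- which(v == "C") - 1L       # 0-based, C on plus strand
    pm <- which(v == "G") - 1L       # C on minus strand
    dt <- data.table::data.table(
      chrom = cn,
      pos = c(pp, pm),
      strand = rep(c("+", "-"), c(length(pp), length(pm))))
    dt[, context := classify_context_chrom(v, pos, strand)]
    dt[context != "incomplete"]
  })
  out <- data.table::rbindlist(parts)
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

# ---- methylome tables -------------------------------------------------------

#' Construct a per-cytosine methylation count table
#'
#' @param dt data.frame/data.table with columns `chrom`, `pos` (0-based),
#'   `strand`, `context`, `meth`, `total`.
#' @param library_id Label for the library.
#' @return A `MethylomeTable` (a keyed `data.table`), sorted by
#'   `(chrom, pos, strand)` with invariants enforced: `meth <= total`,
#'   no duplicated `(chrom, pos, strand)`.
#' @export
methylome_table <- function(dt, library_id = "library") {
  dt <- data.table::as.data.table(dt)
  need <- c("chrom", "pos", "strand", "context", "meth", "total")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing methylome columns: ",
                         paste(miss, collapse = ", "))
  if (any(dt$meth < 0 | dt$total < 0)) stop("negative counts")
  if (any(dt$meth > dt$total)) stop("meth > total; filter rows upstream")
  if (!all(dt$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (!all(dt$context %in% VALID_CONTEXTS)) stop("invalid context value")
  data.table::setorder(dt, chrom, pos, strand)
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
    stop("duplicate (chrom, pos, strand) rows in methylome table")
  data.table::setattr(dt, "library_id", library_id)
  data.table::setattr(dt, "class",
                      c("MethylomeTable", class(data.table::data.table())))
  dt[]
}

#' Read a per-cytosine methylation TSV
#'
#' Expected tab-separated columns (with header): `chrom`, `pos` (1-based),
#' `strand`, `context`, `count_methylated`, `count_total`. Rows with
#' `count_methylated > count_total` are dropped with a warning; any other
#' malformed content is an error. Gzip-transparent.
#'
#' @param path File path.
#' @param library_id Library label; defaults to the file name.
#' @return A `MethylomeTable` with 0-based positions.
#' @export
read_methylome_tsv <- function(path, library_id = NULL) {
  if (is.null(library_id))
    library_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  dt <- if (file.size(path) == 0) data.table::data.table() else
    data.table::fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = c(1, 3, 4)))
  if (nrow(dt) == 0) {
    dt <- data.table::data.table(chrom = character(), pos = integer(),
                                 strand = character(), context = character(),
                                 meth = integer(), total = integer())
    return(methylome_table(dt, library_id))
  }
  need <- c("chrom", "pos", "strand", "context",
            "count_methylated", "count_total")
  if (!all(need %in% names(dt)))
    stop("methylome TSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(dt$count_methylated > dt$count_total)
  if (length(bad)) {
    warning(length(bad), " row(s) with count_methylated > count_total ",
            "dropped (first at data line ", bad[1], ")")
    dt <- dt[-bad]
  }
  if (any(dt$pos < 1)) stop("positions must be 1-based (>= 1), line ",
                            which(dt$pos < 1)[1])
  out <- dt[, .(chrom, pos = as.integer(pos) - 1L, strand, context,
                meth = as.integer(count_methylated),
                total = as.integer(count_total))]
  methylome_table(out, library_id)
}

#' Write a methylome table as TSV (1-based positions)
#' @param mt A `MethylomeTable`.
#' @param path Output path; `.gz` suffix compresses.
#' @export
write_methylome_tsv <- function(mt, path) {
  out <- data.table::data.table(
    chrom = mt$chrom, pos = mt$pos + 1L, strand = mt$strand,
    context = mt$context, count_methylated = mt$meth,
    count_total = mt$total)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

# ---- aligned-read BED -------------------------------------------------------

#' Read aligned reads from BED6
#'
#' BED6 dialect: the name column carries the uniqueness flag (`"U"` unique /
#' `"M"` multi-mapping) and the score column the multiplicity (number of
#' identical copies observed). Rows with `end <= start` are dropped with a
#' warning.
#'
#' @param path BED file (gzip-transparent).
#' @return A [GenomicRanges::GRanges] with metadata columns `is_unique`
#'   (logical) and `multiplicity` (integer).
#' @export
read_bed_reads <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "name", "score", "strand"))
  if (nrow(dt)) {
    bad <- which(dt$end <= dt$start)
    if (length(bad)) {
      warning(length(bad), " BED row(s) with end <= start dropped")
      dt <- dt[-bad]
    }
    if (!all(dt$name %in% c("U", "M")))
      stop("BED name column must be 'U' (unique) or 'M' (multi)")
    if (any(dt$score < 1)) stop("multiplicity (score) must be >= 1")
  }
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = ifelse(dt$strand == ".", "*", dt$strand),
    is_unique = dt$name == "U",
    multiplicity = as.integer(dt$score))
}

#' Write intervals or reads as BED6
#'
#' Inverse of [read_bed_reads()]: `is_unique`/`multiplicity` metadata columns
#' populate name/score when present, else `"U"`/1.
#'
#' @param gr A `GRanges`.
#' @param path Output path; `.gz` suffix compresses.
#' @export
write_bed <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  uniq <- if ("is_unique" %in% names(mc)) mc$is_unique else TRUE
  mult <- if ("multiplicity" %in% names(mc)) mc$multiplicity else 1L
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = ifelse(uniq, "U", "M"),
    score = as.integer(mult),
    strand = as.character(GenomicRanges::strand(gr)))
  dt[strand == "*", strand := "."]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---- gene annotation --------------------------------------------------------

#' Read protein-coding gene models from GFF3
#'
#' Keeps `gene` features; when a `gene_biotype`/`biotype` attribute is
#' present only `protein_coding` genes are retained. Features without
#' coordinates are skipped with a warning by the underlying parser.
#'
#' @param path GFF3 file.
#' @return `GRanges` with metadata columns `gene_id` and `tss`
#'   (0-based position of the transcription start site; equals the interval
#'   start on `+`, interval end - 1 on `-`).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  bt <- if ("gene_biotype" %in% names(mc)) mc$gene_biotype
        else if ("biotype" %in% names(mc)) mc$biotype else NULL
  if (!is.null(bt)) gr <- gr[is.na(bt) | bt == "protein_coding"]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  out <- GenomicRanges::granges(gr)
  out$gene_id <- as.character(ids)
  out$tss <- gene_tss(out)
  out
}

# 0-based TSS: start for +, end-1 for - (both half-open internal convention)
gene_tss <- function(genes) {
  plus <- as.character(GenomicRanges::strand(genes)) != "-"
  ifelse(plus, GenomicRanges::start(genes) - 1L, GenomicRanges::end(genes) - 1L)
}

#' Write gene models as GFF3
#' @param genes `GRanges` with a `gene_id` column.
#' @param path Output path.
#' @export
write_gff_genes <- function(genes, path) {
  out <- GenomicRanges::granges(genes)
  out$source <- "rddmr"
  out$type <- "gene"
  out$ID <- genes$gene_id
  out$gene_biotype <- "protein_coding"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

# ---- misc helpers -----------------------------------------------------------

# GRanges from 0-based half-open columns
gr0 <- function(chrom, start, end, strand = "*", seqinfo = NULL) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = rep(strand, length.out = length(chrom)), seqinfo = seqinfo)
}

# 0-based start/end of a GRanges
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)

genome_seqinfo <- function(genome) {
  GenomeInfoDb_ok <- requireNamespace("GenomeInfoDb", quietly = TRUE)
  w <- if (methods::is(genome, "DNAStringSet")) IRanges::width(genome)
       else nchar(genome)
  nm <- names(genome)
  if (GenomeInfoDb_ok) GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = w)
  else NULL
}
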