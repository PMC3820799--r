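---
title: "Methods: CHH hypomethylation DMR calling and multi-assay integration"
author: "rddmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CHH hypomethylation DMR calling and multi-assay integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`rddmr` detects regions of reduced CHH-context DNA methylation in a mutant
bisulfite library relative to a group of wild-type replicates, and relates
those regions to gene annotation, H3K4 methylation ChIP-seq density, 24-nt
siRNA abundance and mRNA expression. CHH methylation is asymmetric and must
be continuously re-deposited by the RdDM pathway, so localized CHH loss is
the most direct genomic readout of a perturbed pathway component.

## The DMR caller, step by step

**Assayed sites.** A CHH cytosine enters the analysis only when its total
read count is at least `min_cov = 2` in a *strict majority* of wild-type
libraries and in the mutant library. With the default four wild-type
replicates, a majority means at least three; two of four does not qualify.
Requiring the mutant as well prevents calls driven by missing mutant data.

**Smoothing.** Per-site methylation proportions are noisy at 2-8x coverage;
a single CHH site carries almost no information alone. Each track (every
wild-type replicate, the replicate-mean wild-type track, and the mutant) is
smoothed by a tricube-kernel weighted mean over a +/-500 bp window; when a
window holds fewer than `min_sites_smooth = 10` retained sites it is doubled
symmetrically until it does (or spans the chromosome). The kernel distance
is scaled by `half_width + 1` so edge sites keep positive weight; the
smoother therefore preserves constants exactly, returns the raw value at an
isolated site, and transitions monotonically across a step — all asserted in
the test suite. Chromosomes with fewer than 10 retained sites are emitted
unsmoothed with a warning rather than dropped.

**Variance from the wild-type group.** At every site the local SD across the
smoothed wild-type replicate values estimates how much smoothed tracks vary
when nothing is happening biologically. Because replicates can agree almost
exactly in quiet regions, the SD is floored at its genome-wide median
(`sigma_floor`); without the floor, near-zero denominators would manufacture
huge statistics from trivial differences.

**Site statistic and segmentation.** `t = (mu_WT - mu_mut) / max(sigma,
sigma_floor)`, positive where the mutant has lost methylation. Maximal runs
of consecutive assayed sites with `|t| > 2`, uniform sign and inter-site
gaps of at most `max_gap = 300` bp become candidates; the candidate interval
spans the first to one past the last member site.

**Filter cascade.** A candidate is reported when it covers at least 20
assayed CHH cytosines, its mean *raw* (unsmoothed) methylation difference is
at least 0.1, and the magnitude of its area statistic (the sum of member
site statistics) is at least 100. Ties at every threshold are retained
(`>=` semantics). Only hypomethylated regions are reported by default;
`direction = "hyper"` or `"both"` is available. Note the area filter is the
binding one for marginal regions: 20 sites just past `|t| = 2` give
`|area| ~ 40`, so a region needs either more sites or stronger per-site
evidence to reach 100.

**Audit.** `audit_dmrs()` recomputes every clause for an emitted (or
hand-provided) region from the raw inputs and names any violated clause;
the pipeline runs it on its own output and aborts on failure.

## Open design choices and how they were resolved

* **Kernel and bandwidth.** Smoothing-based bisulfite DMR callers (BSmooth
  and its relatives) use local-likelihood fits whose CHH-specific parameters
  are rarely reported. The tricube kernel with 500 bp half-width and a
  10-site minimum is this package's own deterministic, documented choice;
  it approximates local-likelihood smoothing and is pinned down by the
  constant / isolated / step properties in the tests.
* **Segmentation gap.** 300 bp between member sites; a convention this
  package fixes and exposes as a parameter.
* **Raw vs smoothed mean difference.** The 0.1 filter is computed on raw
  per-site proportions (wild-type replicate mean minus mutant), so it
  measures effect size rather than smoother output.
* **Replicate pooling.** The wild-type group track smooths the per-site mean
  of replicate proportions over replicates with nonzero coverage.
* **Sigma floor.** Genome-wide median of the local SD, required for
  well-defined statistics where replicates agree exactly.
* **CCG asymmetry.** Context classification follows the two downstream bases
  on the site's own strand. CG and CAG/CTG sites pair across strands; a CCG
  site is CHG on its strand while its partner reads CGG and classifies CG.
  Sites with fewer than two downstream bases (chromosome ends) are excluded.

## Signal quantification conventions

Duplicate collapsing treats `(chrom, start, end, strand)` as read identity:
cap 1 removes PCR/optical duplicates for ChIP/mRNA/bisulfite libraries; cap
100 keeps up to 100 identical sRNA reads because sRNA duplication is
biological signal. Because identity includes coordinates, per-position and
per-region capping coincide. RPKM counts multiplicity-weighted *unique*
reads overlapping a region by >= 1 bp, normalized by region length and by
`total_mapped`, which for sRNA includes multi-mapping reads. DMR windows are
the 1000 bp centred on `floor((start+end)/2)`, clipped at chromosome bounds
with the denominator corrected to the realized width. Metaplots scale region
bodies to a fixed bin count (fractional bins for very short regions) with
absolute-bp flank bins, averaging bins across regions with equal region
weight. Mann-Whitney U uses exact enumeration when `n1 + n2 <= 12` without
ties, otherwise the normal approximation with tie and continuity correction;
tests are two-sided with the direction reported alongside, so one-sided
conventions remain recoverable. Promoters are the 1 kb immediately upstream of the
TSS (the common Arabidopsis convention, configurable); expression ratios are
`log2((cpm_mut + 1)/(cpm_wt + 1))`.

# The synthetic-data generator

The generator emulates the *statistical structure* the analysis assumes, not
real sequencing:

* Uniform random genome (default two 1-Mb chromosomes), every cytosine
  catalogued with its context.
* Methylomes: per-site coverage ~ Poisson(8); methylated counts ~
  Binomial(coverage, p) with p ~ Beta(mean, concentration 30) per site and
  library — beta-binomial overdispersion of the kind real methylomes show
  and the variance estimation must tolerate. Regional means: CHH 0.4, CHG
  0.6, CG 0.85, emulating a methylated, RdDM-target-like compartment (0.4
  is the wild-type CHH level at target regions; genome-wide Arabidopsis CHH
  is much lower, see limitations). Fifty non-overlapping 1-kb implants, each
  with >= 30 CHH sites, reduce the *mutant* CHH mean by `dmr_effect = 0.3`;
  wild-type replicates share means, CG/CHG are untouched.
* Genes: non-overlapping models at 0.25 genes/kb; a configurable fraction of
  implants receives a gene within 300 bp of one edge, emulating
  hypomethylated regions lying close to genes; per-gene expression rates
  (Gamma, mean 1) are fixed once so genotypes share them.
* Reads: ChIP draws 50-nt read starts from background plus a 5-fold rate in
  the 500 bp downstream of each TSS (5'-enriched H3K4), with the mutant
  adding `h3k4_gain`-fold rate inside implants; sRNA reads (18-28 nt, 24-nt
  mode) are confined to implant clusters plus background clusters placed
  away from implants, with geometric duplication (mean 20, so the 100-read
  cap is actually exercised), a 20% multi-mapping fraction, and the mutant's
  implant cluster rate thinned by `srna_depletion`; mRNA reads fall only in
  gene bodies at the shared per-gene rates.
* Every stage derives its RNG stream from `seed` plus a fixed offset; fixed
  seed implies byte-identical outputs, which the pipeline manifest checks
  via MD5.

A green recovery test therefore establishes that the caller finds regions of
the implanted size and effect at the simulated coverage, with the stated
false-discovery behavior under the null — it does not establish performance
on real bisulfite data with mappability gaps, conversion errors, copy-number
variation or context misassignment, none of which are simulated.

# Numerical and degenerate-input conventions

Internal coordinates are 0-based half-open everywhere; 1-based coordinates
appear only in the TSV/GFF3 dialects (and inside GRanges objects, whose
constructors perform the shift). Overlap means >= 1 shared base under
half-open arithmetic, so abutting intervals do not overlap. Midpoints of
odd-width regions floor. Methylome rows with `meth > total` are dropped with
a warning; duplicate `(chrom, pos, strand)` rows are an error, since
upstream callers emit one row per site. Zero wild-type libraries, empty
samples, degenerate variances, sub-1-kb chromosomes, unplaceable implants
and unknown assay labels are errors naming the offending input. Empty
inputs otherwise propagate as empty outputs (no candidates, zero densities).

# Known limitations

* The uniform-background methylation world is far simpler than a real
  pericentromere; recovery numbers are an upper bound on real-data
  performance.
* One mutant per methylome table; combinatorial genotypes are emulated by
  larger effects at shared implants.
* Gene counting is interval-level (the generator confines mRNA reads to
  gene bodies), not exon-aware.
* The smoothing bandwidth, kernel and segmentation gap have no
  community-standard values for CHH data; the defaults here are design
  decisions, and all of them are exposed as parameters.
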