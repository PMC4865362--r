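---
title: "Methods: spike-in calibrated TAB-seq 5hmC quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in calibrated TAB-seq 5hmC quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

TAB-seq reads a reference cytosine as C (a "protected" call) when the base
was 5hmC and beta-glucosyltransferase protected it from TET oxidation, or
when bisulfite conversion failed. The package works entirely at the level of
per-cytosine call tables: `(chrom, pos, strand, context, protected, total)`,
positions 0-based, contexts `CG`/`CHG`/`CHH` derived from the reference on
the strand of the cytosine. Only CG-context calls enter 5hmC quantification;
non-CG calls serve as a conversion control. Calls are stored per strand and
the two cytosines of a CG dinucleotide are never merged: every downstream
quantity pools read counts, so merging would change nothing except hide
strand-level bookkeeping errors.

Every estimator in the package is a **weighted (read-pooled) level**:

$$\hat p = \frac{\sum_i \text{protected}_i}{\sum_i \text{total}_i}$$

over the selected sites, never a mean of per-site ratios. Site-averaging
would weight a site covered by one read as heavily as one covered by fifty;
at 0.2–1x genome-equivalent coverage almost all covered sites carry one or
two reads, where per-site ratios are nearly meaningless.

Three spike-in calibration rates share this form:

* `nonconv_5mC` — protected fraction at CG sites of a fully 5mC-methylated
  lambda control: the chance a 5mC survives TET oxidation plus bisulfite.
* `nonconv_C` — protected fraction at genomic non-CG (CHG + CHH) cytosines:
  the conversion failure rate of unmodified cytosine.
* `protection_rate` — protected fraction at CG sites of a fully 5hmC pUC19
  control: the chance a true 5hmC is actually read as C.

The global level of a sample is `%5hmCG = 100 * Σprotected / Σtotal` over
all CG calls; the scaled level divides by the sample's own protection rate
(rates are strictly per sample — protection efficiency varies between
library preparations, which is the reason the spike-in exists). No
background subtraction of the non-conversion floor is applied to the global
level: the raw and protection-scaled values are reported side by side with
the non-conversion rates as quality metrics. Scaled values above 100% are
capped with a warning rather than silently reported.

The published count table this arithmetic reproduces has pooled counts of
order $10^5$ protected in $4 \times 10^6$ total, so two populations are
compared with a Pearson chi-square (df = 1) on the 2x2 protected/converted
table, without Yates continuity correction — at these counts the correction
is immaterial. The statistic is computed in closed form and the test suite
cross-checks it against `stats::chisq.test(correct = FALSE)` and against the
squared two-proportion z statistic. Raw p-values are reported; with only a
handful of pairwise comparisons, multiplicity correction is left to the
caller.

## Expression quintiles

RNA-seq read counts grow with a gene's exonic length, so each gene's
expression, averaged over the available samples (16 in the emulated design),
is divided by its total exonic length before ranking. Genes are sorted
ascending by `(score, gene_id)` — ties broken lexicographically in the C
locale so the partition is reproducible across platforms — and cut into five
classes whose sizes differ by at most one. When `n mod 5 != 0` the extra
genes go to the *lowest* quintiles; any placement satisfies the published
size range (5,064–5,065 at n = 25,321), and a fixed rule keeps the
assignment deterministic. Zero-expression genes are retained in quintile 1:
the source gene list is already filtered to expressed transcripts and no
further threshold is documented, so none is applied.

## Metagene binning

Each gene contributes 60 intervals in its own 5'→3' orientation: 20 upstream
flank bins (`UTSS`), 20 gene-body bins (`GB`), 20 downstream flank bins
(`DTTS`). Flank bins have fixed width (default 5,000 bp — 100 kb per side);
body bins partition the gene span `[start, end)` by the floor rule: bin *k*
covers `[floor(kL/20), floor((k+1)L/20))` from the TSS. The rule is
deterministic, gap-free and overlap-free for any gene length ≥ 20 bp;
shorter genes are skipped with a log message. For minus-strand genes all
bins are mirrored, so `UTSS` bin 0 is always farthest upstream of the TSS —
upstream is a strand-relative notion, and profiles from the two strands
would otherwise be averaged back to front. Flank bins running off a contig
edge are clipped and flagged, never dropped; flanks overlapping neighbouring
genes are deliberately not masked (gene-dense regions contribute their
neighbours' signal to flanks, a property of the method, not a bug of the
implementation).

Within a quintile, bin counts are pooled across member genes before
dividing — the read-weighted convention again. A gene-averaged variant
(`gene_average = TRUE`) is provided for sensitivity analysis; it weights
every covered gene equally regardless of coverage. A bin with zero pooled
coverage yields a *missing* level, never 0 — at 0.2x coverage, conflating
"no data" with "no 5hmC" would drag every profile toward zero.

Coverage robustness is assessed by binomial subsampling of the call table:
each site's coverage is thinned `Binomial(total, fraction)` and the
protected count follows by a hypergeometric draw, which is exactly the
distribution obtained by retaining each original read independently. Sites
reaching zero coverage are removed. The subsample is seeded and leaves the
caller's RNG stream untouched.

## The synthetic-data generator

`simulate_dataset()` emulates the study design the pipeline targets: a
two-chromosome 1 Mb toy genome (GC 0.42), 200 non-overlapping genes with
log-normal lengths (median 3 kb), a 16-sample log-normal expression matrix,
fully-5mC lambda (5 kb) and fully-5hmC pUC19 (2,686 bp, the real plasmid
length) spike-ins at 30x, and Poisson(coverage) read depth per cytosine
site with binomial protected counts.

Two modelling choices deserve emphasis:

* **Site-level read model.** Reads are never simulated as fragments; the
  pipeline consumes call tables, and every estimator depends only on the
  per-site counts, so read geometry would add cost without adding test
  power.
* **Per-read protected-call probabilities.** The per-quintile gene-body
  parameters (defaults 0.010, 0.017, 0.024, 0.031, 0.038 for quintiles 1–5)
  and the background CG parameter (0.020) are *apparent* probabilities that
  a read reports C, with assay noise folded in. This makes the configured
  quintile-5 : quintile-1 ratio (3.8) exactly the quantity the pipeline's
  fold-change estimator targets, and it reproduces the qualitative
  published pattern in which the lowest quintile's gene bodies fall *below*
  the flanking background. The spike-ins, by contrast, follow the assay
  chemistry exactly: lambda CG sites read C at `nonconv_5mC` (0.03), pUC19
  CG sites at `protection_rate` (0.52, matching the ratio of the published
  raw to scaled global levels), and all non-CG cytosines at `nonconv_C`
  (0.005). An explicit true-5hmC-fraction parameterisation was rejected
  because a gene-body apparent level below the non-conversion floor — which
  the published profiles show — has no representation in it.

The expression generator places each gene's exon-normalised mean score in a
disjoint per-quintile band and rescales the per-sample noise so the sample
mean is exact; re-running the quintile assignment on the emitted table
therefore recovers the configured labels with certainty, giving the metagene
tests a known partition rather than a probabilistic one.

For toy chromosomes the 5 kb flank bin is scaled down (simulation default
100 bp, i.e. 2 kb flanks per side) via the same `flank_bin_size` parameter
the metagene module exposes; genome-scale analyses keep the 5 kb default.

What the generator does *not* emulate: realistic genome composition or CpG
islands, fragment-level artefacts (PCR duplicates, mapping bias,
sequencing-error substitutions beyond the conversion chemistry), TSS-shaped
within-gene structure, or correlated methylation between neighbouring sites.
Passing tests therefore demonstrate that the *estimators* are correct and
stable under sampling noise and depth, not that real tissue data would be
free of alignment- or chemistry-level artefacts.

## Numerical and interface choices

* Coordinates are 0-based half-open everywhere; BED is native, GFF3 starts
  are decremented on read. One convention eliminates off-by-one bin edges.
* Duplicate `(chrom, pos, strand)` call rows are an error, never merged.
* Published-table percentages are displayed at two decimals with half-even
  rounding; all internal arithmetic keeps full precision.
* The published "total 5hmCG / total CG" counting convention is taken to be
  read-observation-level, consistent with the weighted-level method the
  source cites; a site-level variant would change the totals but not the
  estimator family.
* Sequencing coverage in genome equivalents is the mean read depth per
  reference cytosine (`Σtotal / #cytosine sites`), used as the
  genome-equivalents proxy.
* Degenerate inputs raise typed validation errors (empty CG selection,
  zero-coverage rate, zero chi-square margin, uncovered low quintile in a
  fold change) rather than returning NaN/Inf.
* User-input failures carry the condition class
  `hydroxymeta_validation_error`, which the command-line wrapper maps to
  exit code 2 (internal errors map to 1). The CLI writes a manifest
  (parameters, input checksums, package version, no timestamp) so identical
  re-runs are byte-identical.
* Metagene profiles are emitted raw by default; an optional `scale`
  argument divides levels by a protection rate. The fold change is invariant
  either way, since the rate cancels in the ratio.

## Problem sizes

The test suite runs synthetic genomes of 60 kb (10 genes) for unit and
property tests, and the full default scale (1 Mb, 200 genes) for the
fold-change recovery (10 replicate seeds at 1x) and the subsampling analog
(one 13x dataset thinned to 0.2x). The calibration-coverage study uses 100
replicates of the 60 kb configuration. The acceptance script repeats the
fold-change recovery at the default scale. These sizes were chosen so the
pooled low-quintile gene body carries roughly 10^4 read observations at 1x —
enough that the fold-change estimator's sampling error (~10% per replicate,
~3% for the 10-seed mean) sits inside the tolerances being checked.

## Known limitations

* TAB-seq cannot separate C from 5mC; the package accordingly estimates
  only 5hmC and makes no attempt at per-site statistical 5hmC calling —
  all published quantities it reproduces are aggregates.
* The exact-binomial coverage study is statistically tight: with a 99% CI
  checked over 100 replicates, a correct estimator still misses twice or
  more in a nontrivial fraction of seed sets, because the exact interval's
  true coverage approaches its nominal level at large counts.
* GFF3 exon features are associated to genes through a direct `Parent`
  link; transcript-mediated hierarchies collapse to the gene span unless
  exons name the gene as parent.
* Enhancer-centric profiles, profile smoothing, and per-bin differential
  testing are out of scope.
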