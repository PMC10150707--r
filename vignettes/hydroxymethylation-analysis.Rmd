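---
title: "Genome-wide 5hmC profiling and differential hydroxymethylation with hydroxyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide 5hmC profiling and differential hydroxymethylation with hydroxyscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`hydroxyscan` implements a reduced-representation 5-hydroxymethylcytosine
(5hmC) profiling analysis. In an RRHP library, genomic DNA is digested
with MspI (which cuts C^CGG regardless of CpG methylation), adapters are
ligated at the cut sites, 5hmC at the junction is glucosylated, and a
second digestion removes fragments whose junction cytosine was not
protected. Only 5hmC-protected fragments amplify, so a sequenced read
beginning with the CCGG signature is direct evidence of
hydroxymethylation at that MspI site, and per-site read counts are a
quantitative 5hmC signal.

The analysis chain is:

1. **Site universe** — every CCGG occurrence on the forward strand of the
   reference. CCGG is palindromic, so sites are strand-collapsed: reads
   from either fragment end attribute to the same motif.
2. **Read quantification** — reads are kept iff they begin with the P5
   motif (`CCGG`); one terminal P7 remnant (`CG`) is removed, trailing
   bases below a Phred floor (default 20) are trimmed, and reads shorter
   than 35 bases are discarded. Kept reads are placed by exact match
   against the reference in either orientation; reads matching no site,
   or more than one, stay unassigned.
3. **Normalization** — quantile normalization *within* each cell type
   (mean of order statistics; tied entries share the mean of their tied
   target values); sites with fewer than 10 normalized counts in fewer
   than 3 samples of both cell types are removed; retained counts become
   log2-CPM, `log2((c + 0.5)/(L + 1) * 1e6)`, with a lowess mean-variance
   trend providing voom-style inverse-fourth-power precision weights.
4. **Per-site inference** — the primary statistic is the classical paired
   t-test on log2-CPM differences within subjects (`t = mean(d)/(sd(d)/sqrt(n))`,
   `df = n - 1`). An empirical-Bayes moderated t is computed alongside:
   per-site variances are modelled as scaled F around a prior
   `(d0, s0^2)` estimated by digamma/trigamma moment matching on
   `log s^2`, posterior variances are
   `(d0 s0^2 + d s^2)/(d0 + d)` on `d + d0` degrees of freedom.
5. **Volcano and direction** — down iff `log2FC < -1` and `p < 0.05`, up
   iff `log2FC > 1` and `p < 0.05` (strict inequalities); the
   fraction of negative fold changes overall and among nominal hits
   summarizes a global shift. FDR is Benjamini–Hochberg.
6. **DhMR scan** — one-sided t p-values are combined over sliding windows
   of nine sequential sites (step one site, never crossing chromosomes,
   spans of 50 kb or more skipped) with Fisher's statistic
   `X^2 = -2 * sum(log p_i)` on `2k` degrees of freedom. Family-wise
   correction uses the number of *non-overlapping* bins,
   `ceiling(n_sites / 9)`, not the number of sliding windows. Chains of
   overlapping windows collapse to the window with the smallest combined
   p (leftmost on ties).
7. **Clustering** — two-way UPGMA on Pearson correlation dissimilarity
   (`1 - r`) of the top differentiated sites (`p < 0.01`), with row
   Z-scores as the heatmap matrix.

# Assumptions

* Paired design: each subject contributes one sample per cell state, and
  the paired t assumes within-subject differences are approximately
  Gaussian on the log2-CPM scale.
* Fisher's combination treats the nine member p-values as independent
  under the null; neighbouring sites in real data are correlated, so the
  Bonferroni-over-bins threshold is the intended (conservative at the
  bin level) control, and combined p-values of overlapping windows are
  not themselves multiplicity-adjusted.
* Exact-match placement assumes reads without sequencing errors; data
  aligned externally enter via `import_alignments()` (SAM or BED).

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p5_motif`, `p7_adapter` | `CCGG`, `CG` | protected-site signature and 3' remnant |
| `min_length` | 35 bases | post-trim read length floor |
| `quality_floor` | Phred 20 | 3' trailing-base trim threshold |
| `promoter_span` | 1000 bases | strictly upstream of each transcript TSS |
| `shore_span`, `shelf_span` | 2000, 4000 bases | CpG-island shore/shelf bands |
| `min_count`, `min_samples` | 10, 3 | low-count filter, per cell-type group |
| `prior_count`, `libsize_adjust` | 0.5, +1 | log2-CPM offsets |
| `fc_thresh`, `p_thresh` | 1, 0.05 | volcano rule |
| `k`, `max_span` | 9 sites, 50 kb (exclusive) | DhMR window |
| `p_floor` | `.Machine$double.xmin` | clamp before `log(p)` |
| `cluster p_thresh` | 0.01 | top-site selection |

# Numerical and design choices

* **Feature precedence.** Site classes are made mutually exclusive by
  5'UTR > 3'UTR > exon > intron > promoter > intergenic, evaluated over
  all overlapping transcripts of all genes. Genic context outranks
  another gene's promoter; the order is a package choice (configurable)
  since mutually exclusive fractions do not define one.
* **Quantile-normalization ties.** With integer counts, tied entries
  receive the mean of the target quantiles they span. Consequently the
  "sorted columns identical" identity holds exactly on tie-free input
  and approximately otherwise; rank order is preserved up to ties.
* **Degenerate sites.** Zero-variance differences yield `t = 0`,
  `p = 1` and a flag rather than NaN, and one-sided p-values of flagged
  sites are 0.5, so they are uninformative in window combination.
* **EB prior edge case.** When `log s^2` shows no excess variability
  beyond sampling noise, `d0` is infinite and the common variance is the
  arithmetic mean of the observed variances, so identical input
  variances shrink to themselves.
* **UPGMA conventions.** Join heights use d/2 (ultrametric tree height);
  ties break toward the lowest leaf index. Both are recorded on the
  result; `as_hclust()` doubles heights for direct comparison with
  `hclust(..., method = "average")`.
* **Window span.** A window's span is `last - first + 1` bases (the
  printed "size" convention for a locus) and must be strictly below
  `max_span`.
* **Contrast orientation** is always recorded on results; the sign of a
  fold change is never interpreted without it.
* **BD-style case/sibling comparisons.** The pairing of the disease
  contrast is not fixed by the design; both the paired machinery (pair =
  sibling pair) and unpaired Welch/pooled t (`unpaired_t()`) are
  provided, flagged in output.

# The synthetic-data generator

Real RRHP patient data are not redistributable, so every stage is
exercised on synthetic inputs with the statistical structure the
analysis assumes:

* `simulate_genome()` plants CCGG motifs as a minimum-gap Poisson
  process in background sequence scrubbed of accidental motifs, plus
  disjoint CpG islands and stranded gene models (5'UTR/CDS/intron/3'UTR),
  so the digest recovers exactly the planted site list.
* `simulate_reads()` emits Poisson(depth x level) reads per site — the
  CCGG-prefixed genomic sequence in either fragment orientation with a
  terminal `CG` remnant — plus a stated fraction of decoy reads lacking
  the prefix, with exact bookkeeping for round-trip tests.
* `simulate_counts()` draws negative-binomial counts (default dispersion
  0.05) around log-normal per-site baselines (median 50 counts,
  sdlog 1), a Gaussian subject random effect (sd 0.3 log2 units) shared
  by each subject's two samples — inducing the within-pair correlation
  the paired t exploits — and cell-state effects: a global log2 shift
  (default -0.3, the global NSC hypo-hydroxymethylation the design
  targets), site-specific effects for a 2% subset, and planted
  9-site DhMR runs with a common effect.

**Library sizes.** The simulated matrix models the *filtered analysis
subset* of a much larger site universe, so the carried library sizes are
exogenous full-library depths (default 5e6 x a per-sample factor in
[0.9, 1.1]) rather than the subset's column sums. This is what makes a
global shift observable in CPM space: normalizing a self-contained
matrix by its own column sums would cancel any uniform shift exactly.
Exported count tables keep these sizes in a `# library_sizes` header.

**What the generator does not emulate:** sequencing errors beyond
decoys, PCR duplicates, GC or fragment-length bias, correlated
neighbouring sites under the null, batch structure, and real CpG-island
sequence composition (islands are coordinates, not CG-rich sequence).
Passing tests therefore demonstrate correctness of the computations and
calibration under the stated model, not robustness to those artefacts.

**Study-condition defaults** mirror the emulated design: 4 subjects
(2 cases with same-sex age-matched sibling pairs), two cell states per
subject (8 samples), 20,000 sites for count-level analyses (desk-scale
stand-in for the filtered universe), read-level demos on ~100 kb
references with ~1 site per 500 bp.

# Validation problem sizes

The test suite and acceptance script recompute, among others: the two
non-overlapping-bin counts for the published site universes
(124,603 -> 13,845; 101,673 -> 11,297); Fisher combination against an
independent gamma-survival oracle (1,000 random nine-site windows,
agreement to 1e-10); type-I calibration of the paired t (4 pairs,
10,000 Gaussian null sites, rejection in [0.043, 0.057]) and of window
combination over non-overlapping null bins (9,000 sites, [0.036,
0.064]); recovery of a planted -0.3 global shift within +/-0.05 (20,000
sites, dispersion 0.05); the planted 9-site DhMR ranked top in >= 18 of
20 replicates at 5,000 sites each; EB prior recovery (d0 within 30%,
s0^2 within 10%, 5,000 sites); and exact read round trips including
decoy accounting. Each number is produced by running the package at
those sizes; none is asserted from the literature.

# Known limitations

* Exact placement is intended for simulated or error-free reads; real
  data should be aligned externally and imported.
* The mean-variance trend weights feed the moderated pipeline only; the
  classical paired t operates on unweighted log2-CPM, matching the
  primary-statistic convention.
* With four pairs, covariates (age, sex) nearly saturate the per-site
  design; the default trend design is intercept + cell type, and any
  richer design is the user's explicit choice.
* `collapse_windows()` reports one representative window per overlapping
  chain; it does not merge member sites into wider intervals, and can be
  disabled to inspect all windows.
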