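---
title: "Quantifying translational regulation with riboTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translational regulation with riboTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboTE)
```

## The measurement model

Ribosome profiling (Ribo-seq) sequences the ~26–32 nt mRNA fragments
protected from nuclease digestion by translating ribosomes, giving a
quantitative readout of translation that can be contrasted with matched
RNA-seq.  riboTE starts from per-gene count matrices for the two assays
(read alignment and P-site calling are upstream of this package) and
works through four statistics:

* **FPKM** — fragments per kilobase of effective gene length per million
  library fragments, `C / ((L/1000) * (N/1e6))`.  The effective length
  `L` is the CDS for the RPF assay (ribosomes occupy the coding region)
  and the full transcript (5'UTR + CDS + 3'UTR) for RNA-seq; both choices
  are arguments of `compute_fpkm()` so either denominator can be used.
  The library size `N` defaults to the sample's column sum and can be
  overridden, e.g. with sizes computed after fragment-length filtering.
* **TE** — translational efficiency, the ratio of Ribo-seq FPKM to
  RNA-seq FPKM for a gene in one (condition, replicate) pair.  A
  pseudocount (default 0.5) is added to both FPKM values so TE is defined
  at zero coverage, and genes below a mean RNA FPKM floor (default 1) in
  either condition are flagged excluded rather than classified.
* **ΔTE** — the ratio of treatment TE to control TE, with each
  condition's TE summarised as the geometric mean over replicates
  (equivalently the arithmetic mean of log2 TE — the natural summary for
  a ratio statistic).
* **TE class** — each analysed gene is called TE-up
  (log2 ΔTE ≥ cut and p ≤ α), TE-down (≤ −cut and p ≤ α) or
  TE-insensitive, with defaults α = 0.05 and cut = 1 (two-fold).  These
  thresholds are deliberate package choices exposed in
  `analysis_thresholds()`; published analyses of this kind rarely state
  them, so every one is recorded in the run's `config.yaml`.

The per-gene p-value is a two-sided Welch t-test on replicate log2 TE.
The log scale stabilises the variance of a ratio; an epsilon floor on the
within-group variances keeps degenerate zero-variance replicates finite.
An exact permutation mode (`test_te_change(..., mode = "permutation")`)
enumerates all relabelings of up to 10 replicates and serves as a
small-sample reference: note that with 3+3 replicates its null has only
20 atoms (minimum attainable p = 0.1), so the parametric and permutation
p agree closely for most but not all datasets.

The **nine-quadrant** view trichotomises the RNA (transcriptome) and RPF
(translatome) axes separately — each axis gets its own Welch test and
fold-change gate — yielding labels such as `rna-flat_ribo-up`.  Genes
significant on the ribo axis but flat on the RNA axis are the
*translatome-only* changes, the population a TE analysis exists to find.

## 5'UTR features

Translationally regulated transcripts are repeatedly reported to carry
long, GC-rich, structured 5'UTRs and upstream open reading frames.
`feature_table()` computes per gene:

* `gc5` — 5'UTR GC percent (empty UTRs are missing, never 0);
* `len5`, `len_cds`, `len3` — region lengths in nt;
* `dG5` — the minimum energy of a pseudoknot-free secondary structure
  under a Nussinov-style dynamic program that minimises summed pair
  energies (defaults G:C −3, A:U −2, G:U −1, hairpin loops ≥ 3 nt).
  These are model units that rank structural complexity, not
  nearest-neighbour kcal/mol; the `dG5` column can be replaced with any
  external folder's output if physical energies are needed.  The
  length-normalised `dG5_per_nt` is reported alongside because "overall
  low free energy" conflates length with composition; comparisons run on
  the raw value by default.
* `n_uorf` — the number of AUGs whose first in-frame stop codon lies
  inside the 5'UTR.  Overlapping and nested uORFs count separately per
  start codon; AUGs that run open into the CDS are excluded by default
  (`include_open = TRUE` includes them).

`compare_feature_distributions()` contrasts each feature between the
TE-up and TE-down classes and the insensitive background with the
Mann-Whitney rank-sum test — the conventional choice for these skewed,
heavy-tailed feature distributions.  The implementation uses midranks for
ties; exact enumeration is available up to 12 observations and the
normal approximation (continuity-corrected, tie-corrected variance) is
used for the genome-scale comparisons.

Over-representation of a TE class in annotated gene sets (GO/KEGG-style
GMT files) is tested with the upper-tail hypergeometric probability
computed in log space, with Benjamini–Hochberg FDR across retained sets.
The background universe is the set of analysed (detection-filtered)
genes, not the whole annotation — using all genes would inflate
enrichment of highly expressed categories.

## What the simulator plants, and what it does not

Because matched Ribo-seq/RNA-seq datasets with known truth do not exist,
`simulate_translatome()` generates one with planted structure:

* transcript models over {A, C, G, U}: 5'UTR by per-base GC-probability
  sampling, CDS codon-wise (AUG start, sense codons, one stop), 3'UTR at
  40% GC.  Defaults: baseline 5'UTR GC 50%, lognormal lengths with
  medians 150 nt (5'UTR, sdlog 0.45), 300 nt (3'UTR) and 400 codons
  (CDS) — typical mammalian transcript scales;
* ground-truth TE classes: 10% TE-up (planted ΔTE 4), 10% TE-down
  (ΔTE 0.25); TE-sensitive genes' 5'UTRs are drawn with +10 GC points
  and 1.5× length, mirroring the structured-5'UTR signature the feature
  stage is meant to recover;
* counts: per-gene lognormal abundance (sdlog 1), negative binomial with
  shared dispersion φ (default 0.05; φ = 0 gives Poisson, which the
  validation oracles exploit).  RNA means are identical across
  conditions — treatment enters only through RPF means — so the expected
  ratio of count ratios equals the planted ΔTE exactly;
* RPF lengths: a shifted binomial over 26–32 nt with mode 29, so most
  fragments fall in the 28–30 nt analysis window used by
  `filter_rpf_lengths()`.

Two consequences worth knowing.  First, with column-sum library sizes
and 20% of genes carrying planted RPF effects (net factor 1.225), the
FPKM-based log2 ΔTE of every gene is shifted by −log2(1.225) ≈ −0.29
relative to truth — the same compositional effect any normalisation by
total counts exhibits.  The planted effects (|log2| = 2) are large
enough that classification is barely affected, but insensitive genes sit
at −0.29, not 0.  Raw count ratios, which the simulator's validation
tests use, are unbiased.  Second, the generator makes no attempt to
emulate alignment artifacts, rRNA contamination, codon-level dwell
times, 5'UTR–expression correlations or overdispersion heterogeneity, so
passing recovery tests demonstrate the pipeline's correctness on its own
statistical model, not robustness to every pathology of real libraries.

The planted GC and length shifts are inherited by `dG5`: GC-richer,
longer UTRs fold to lower energies, so a significant `dG5` difference in
the default simulation is expected and real.  The null behaviour of the
folding comparison is therefore validated separately with
`gc_shift_points = 0, len5_shift = 1`, where `dG5` differences should be
(and are) non-significant.

## Numerical and design choices

* Folding DP: energies are small integers, so exact equality against an
  exhaustive structure-enumeration oracle is asserted (not approximate);
  the traceback prefers leaving the 3' base unpaired on ties, making
  structures deterministic.  Cost is O(n³)/O(n²); the Rcpp kernel folds
  a 2000-gene transcriptome (median 5'UTR 150 nt) in seconds.
* Hypergeometric tail: log-space summation with a max-shift, exact
  against brute-force combinatorial sums over the full N ≤ 20 grid.
* Welch test: variance floor 1e-8 on log2 values; fewer than 2
  replicates per condition yields p = 1 with a warning, never an error.
* Classification gates use raw p by default (volcano-style); BH FDR is
  always reported and can gate instead (`gate = "fdr"`).
* Missing values are written as `NA` in every TSV; all writers emit
  headers and all readers validate them by name.
* Determinism: every stochastic stage is a pure function of (config,
  seed); `run_all()` twice with one seed produces byte-identical data
  products (the manifest carries timestamps and is excluded).

Validation problem sizes (chosen to exercise the asymptotics the
methods rely on while keeping the suite quick): folding oracle at 200
sequences ≤ 12 nt; rank-sum enumeration at ≤ 10 observations × 100
instances; TE recovery at 2000 genes × 3+3 replicates × 2×10⁶ fragments,
where planted classes are recovered with ≥ 80% sensitivity at ≤ 10%
false discovery; feature recovery on the same scale.

## Known limitations

* TE is a ratio of normalised means, not a count-model contrast; very
  low-coverage genes are excluded rather than shrunk.
* The folding model ignores stacking, loop entropies and pseudoknots by
  construction.
* uORF counting requires only an AUG and an in-frame stop; it does not
  model initiation context (Kozak) strength.
* The nine-quadrant partition inherits the per-axis tests'
  power; with 3 replicates the flat calls are conservative.
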