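# riboTE

Translational efficiency analysis for matched ribosome-profiling
(Ribo-seq) and RNA-seq experiments.

Treatments that act on translation — differentiation inducers, kinase
inhibitors, stress — can change how efficiently an mRNA is translated
without changing its abundance. Ribo-seq captures the ~26–32 nt
fragments protected by translating ribosomes; contrasted with matched
RNA-seq it separates the translatome from the transcriptome. riboTE
takes per-gene count matrices for the two assays across replicated
control/treatment samples and computes:

* **FPKM** for each assay: `FPKM = C / ((L/1000) × (N/10⁶))` with the
  CDS as effective length for ribosome-protected fragments (RPFs) and
  the full transcript for RNA;
* **translational efficiency** `TE = FPKM(Ribo-seq) / FPKM(RNA-seq)` per
  gene and replicate, and its condition fold change
  `ΔTE = TE(treatment) / TE(control)`;
* a per-gene test on replicate log2 TE (Welch, with an exact permutation
  mode), classifying genes as **TE-up / TE-down / TE-insensitive**;
* the **nine-quadrant** transcriptome × translatome partition and the
  count of translatome-only changes;
* **5′UTR/CDS/3′UTR features** — GC%, lengths, Nussinov folding energy,
  uORF counts — compared between TE classes with Mann-Whitney tests;
* **hypergeometric gene-set enrichment** of any TE class against GMT
  collections, with Benjamini–Hochberg FDR.

A negative-binomial simulator with planted TE effects and 5′UTR feature
shifts provides ground truth, so every stage of the pipeline is
validated by recovery of known signal.

## Worked example

Simulate a 500-gene experiment (3 + 3 replicates, planted ΔTE = 4 in 10%
of genes and ΔTE = 0.25 in another 10%, GC-richer and longer 5′UTRs in
the TE-sensitive genes), then run the analysis:

```r
library(riboTE)

cfg <- sim_config(n_genes = 500, mean_depth = 5e5, seed = 7)
sim <- simulate_translatome(cfg, n_rpf_lengths = 2e4)

# fragment-length filter: 15630 of 20000 fragments in 28-30 nt (78.2%)
keep <- filter_rpf_lengths(sim$rpf_lengths, c(28, 30))

fpkm_rna <- compute_fpkm(sim$rna, effective_lengths(sim$models, "RNA"))
fpkm_rpf <- compute_fpkm(sim$rpf, effective_lengths(sim$models, "RPF"))
te <- te_analysis(fpkm_rpf, fpkm_rna)
table(te$te_class)
#>        down insensitive          up
#>          54         408          38
sum(translatome_only(te$quadrant), na.rm = TRUE)
#> [1] 100
head(te[order(te$p), c("gene_id", "delta_te", "p", "fdr", "te_class")], 3)
#>     gene_id delta_te        p    fdr te_class
#> 248   g0248    4.105 5.82e-05 0.0153       up
#> 233   g0233    0.132 6.10e-05 0.0153     down
#> 377   g0377    0.184 3.75e-04 0.0413     down
```

The planted classes surface directly: genes called TE-up sit near the
planted four-fold ΔTE, and the 100 translatome-only genes are changes
invisible to RNA-seq alone. The planted 5′UTR signature is recovered by
the feature comparisons (TE-down vs insensitive):

```r
ft <- feature_table(sim$models)
cmp <- compare_feature_distributions(ft, te)
cmp[cmp$feature %in% c("gc5", "len5", "dG5") & cmp$group_a == "down", ]
#>   feature group_a     group_b u_statistic  p_value n_a n_b
#> 2     gc5    down insensitive       20266 1.10e-23  54 408
#> 4    len5    down insensitive       16189 2.02e-08  54 408
#> 6     dG5    down insensitive        5378 9.64e-10  54 408
```

TE-down genes have significantly GC-richer (`gc5`), longer (`len5`) and
more structured (lower `dG5`) 5′UTRs — the signature the simulator
planted. Gene-set enrichment of the TE-down class against a toy GMT with
one planted set:

```r
sets <- simulate_gene_sets(sim$truth, seed = 10)
res <- enrich(te$gene_id[which(te$te_class == "down")], sets,
              te$gene_id[!te$excluded])
head(res[, 1:7], 2)
#>                set  k  K  n   N  p_value      fdr
#> 1 planted_down_set 39 50 54 500 1.16e-35 2.32e-34
#> 2    random_set_04  8 50 54 500 1.56e-01 8.14e-01
```

`run_all(pipeline_config(outdir = "run1", seed = 1))` chains all stages
(simulate → quantify → TE → features → enrichment), writes every table
as TSV plus a JSON run manifest, and is byte-reproducible at a fixed
seed. Supply `counts` paths in the config to analyse your own data
instead of simulating.

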