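# small cached synthetic dataset reused across test files
small_te_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 400, mean_depth = 4e5, seed = 101)
      tx <- simulate_transcriptome(cfg)
      cnt <- simulate_counts(tx$models, tx$truth, cfg)
      fpkm_rna <- compute_fpkm(cnt$rna, effective_lengths(tx$models, "RNA"))
      fpkm_rpf <- compute_fpkm(cnt$rpf, effective_lengths(tx$models, "RPF"))
      cache <<- list(cfg = cfg, models = tx$models, truth = tx$truth,
                     rna = cnt$rna, rpf = cnt$rpf,
                     fpkm_rna = fpkm_rna, fpkm_rpf = fpkm_rpf,
                     te = te_analysis(fpkm_rpf, fpkm_rna))
    }
    cache
  }
})

# flip condition labels of a count_matrix (control <-> treatment)
swap_conditions <- function(cm) {
  cm$samples$condition <- ifelse(cm$samples$condition == "control",
                                 "treatment", "control")
  cm
}
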