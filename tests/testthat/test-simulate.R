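test_that("config invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(frac_te_up = 0.7, frac_te_down = 0.6), "<= 1")
  expect_error(sim_config(effect_te_up = 0.5), "effect_te_down < 1")
  expect_error(sim_config(rpf_len_min = 33), "rpf_len_min")
  expect_error(sim_config(base_gc5 = 95, gc_shift_points = 10), "outside")
})

test_that("transcriptome generation is deterministic and bookkeeps classes", {
  cfg <- sim_config(n_genes = 300, seed = 11)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a, b)

  tab <- table(a$truth$true_class)
  expect_identical(sum(tab), 300L)
  expect_equal(unname(tab[["up"]]), 30)
  expect_equal(unname(tab[["down"]]), 30)
  expect_true(all(a$truth$true_delta_te[a$truth$true_class ==
                                          "insensitive"] == 1))

  # structural contract of every CDS
  expect_true(all(nchar(a$models$cds) %% 3 == 0))
  expect_true(all(substr(a$models$cds, 1, 3) == "AUG"))
  last <- substr(a$models$cds, nchar(a$models$cds) - 2, nchar(a$models$cds))
  expect_true(all(last %in% c("UAA", "UAG", "UGA")))
  expect_false(any(grepl("[^ACGU]", c(a$models$utr5, a$models$cds,
                                      a$models$utr3))))
})

test_that("planted GC shift appears in sensitive 5'UTRs at the planted size", {
  cfg <- sim_config(n_genes = 2000, gc_shift_points = 10, seed = 21)
  tx <- simulate_transcriptome(cfg)
  sens <- tx$truth$true_class != "insensitive"
  gap <- mean(gc_percent(tx$models$utr5[sens])) -
    mean(gc_percent(tx$models$utr5[!sens]))
  expect_gt(gap, 9)
  expect_lt(gap, 11)

  # no planted effect: gap vanishes
  cfg0 <- sim_config(n_genes = 2000, gc_shift_points = 0, len5_shift = 1,
                     seed = 22)
  tx0 <- simulate_transcriptome(cfg0)
  sens0 <- tx0$truth$true_class != "insensitive"
  gap0 <- mean(gc_percent(tx0$models$utr5[sens0])) -
    mean(gc_percent(tx0$models$utr5[!sens0]))
  expect_lt(abs(gap0), 2)
  len_ratio <- mean(nchar(tx0$models$utr5[sens0])) /
    mean(nchar(tx0$models$utr5[!sens0]))
  expect_lt(abs(len_ratio - 1), 0.15)
})

test_that("count generation respects depth, determinism and planted effects", {
  cfg <- sim_config(n_genes = 40, mean_depth = 0, seed = 5)
  tx <- simulate_transcriptome(cfg)
  cnt <- simulate_counts(tx$models, tx$truth, cfg)
  expect_true(all(cnt$rna$counts == 0))
  expect_true(all(cnt$rpf$counts == 0))

  cfg <- sim_config(n_genes = 40, mean_depth = 1e5, seed = 5)
  expect_identical(simulate_counts(tx$models, tx$truth, cfg),
                   simulate_counts(tx$models, tx$truth, cfg))
  expect_error(simulate_counts(tx$models[0, ], tx$truth[0, ], cfg), "empty")

  # law of large numbers: Poisson limit, deep library, planted fold 4
  cfg <- sim_config(n_genes = 50, mean_depth = 1e7, dispersion = 0,
                    effect_te_up = 4, seed = 9)
  tx <- simulate_transcriptome(cfg)
  cnt <- simulate_counts(tx$models, tx$truth, cfg)
  ctrl <- cnt$rna$samples$condition == "control"
  ratio <- function(cm) rowSums(cm$counts[, !ctrl]) / rowSums(cm$counts[, ctrl])
  emp_dte <- ratio(cnt$rpf) / ratio(cnt$rna)
  up <- tx$truth$true_class == "up"
  expect_true(all(emp_dte[up] > 3.5 & emp_dte[up] < 4.5))
  ins <- tx$truth$true_class == "insensitive"
  expect_true(all(abs(log2(emp_dte[ins])) < 0.5))
})

test_that("within-class mean log2 delta-TE matches the planted effects", {
  cfg <- sim_config(n_genes = 1000, mean_depth = 2e6, dispersion = 0.01,
                    n_replicates = 3, seed = 31)
  tx <- simulate_transcriptome(cfg)
  cnt <- simulate_counts(tx$models, tx$truth, cfg)
  ctrl <- cnt$rna$samples$condition == "control"
  ratio <- function(cm) rowSums(cm$counts[, !ctrl]) / rowSums(cm$counts[, ctrl])
  l2 <- log2(ratio(cnt$rpf) / ratio(cnt$rna))
  by_class <- tapply(l2, tx$truth$true_class, mean)
  expect_lt(abs(by_class[["up"]] - log2(cfg$effect_te_up)), 0.2)
  expect_lt(abs(by_class[["down"]] - log2(cfg$effect_te_down)), 0.2)
  expect_lt(abs(by_class[["insensitive"]]), 0.2)

  # no leakage into the transcriptome: RNA means condition-invariant
  rna_lfc <- log2(rowMeans(cnt$rna$counts[, !ctrl]) /
                    rowMeans(cnt$rna$counts[, ctrl]))
  expect_lt(abs(mean(rna_lfc[tx$truth$true_class == "up"])), 0.1)
})

test_that("RPF lengths live in the configured window with an interior mode", {
  cfg <- sim_config(seed = 13)
  expect_identical(simulate_rpf_lengths(0, cfg), integer(0))
  expect_error(simulate_rpf_lengths(-1, cfg), ">= 0")
  len <- simulate_rpf_lengths(1e5, cfg)
  expect_gte(min(len), 26)
  expect_lte(max(len), 32)
  in_window <- mean(len >= 28 & len <= 30)
  expect_gt(in_window, 1 - in_window)
  tab <- table(factor(len, levels = 26:32))
  expect_true(names(which.max(tab)) %in% c("28", "29", "30"))
  expect_identical(len, simulate_rpf_lengths(1e5, cfg))
})

test_that("toy gene sets contain one set enriched for the planted class", {
  cfg <- sim_config(n_genes = 500, seed = 17)
  tx <- simulate_transcriptome(cfg)
  sets <- simulate_gene_sets(tx$truth, n_sets = 10, set_size = 40,
                             planted_class = "down", seed = 3)
  expect_length(sets, 10)
  down <- tx$truth$gene_id[tx$truth$true_class == "down"]
  frac_planted <- length(intersect(sets[["planted_down_set"]], down)) / 40
  frac_random <- mean(vapply(sets[-1], function(s)
    length(intersect(s, down)) / length(s), numeric(1)))
  expect_gt(frac_planted, 0.5)
  expect_lt(frac_random, 0.3)
})
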