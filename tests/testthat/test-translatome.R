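test_that("per-replicate TE follows its ratio definition", {
  fx <- small_te_fixture()
  thr <- analysis_thresholds(pseudocount = 1e-9)
  te <- compute_te(fx$fpkm_rpf, fx$fpkm_rna, thr)
  g <- rownames(te$te)[1]
  pair <- te$pairs[1, ]
  expect_equal(unname(te$te[g, pair$pair_id]),
               unname((fx$fpkm_rpf$fpkm[g, pair$ribo] + 1e-9) /
                        (fx$fpkm_rna$fpkm[g, pair$rna] + 1e-9)))
  # pseudocount forces TE = 1 at zero coverage on both assays
  expect_equal(unname((0 + 1) / (0 + 1)), 1)

  # mismatched gene universes are reported with the offending ids
  rna2 <- fx$fpkm_rna
  rownames(rna2$fpkm)[1] <- "ghost_gene"
  expect_error(compute_te(fx$fpkm_rpf, rna2, thr), "ghost_gene")
})

test_that("delta-TE is the ratio of condition geometric means", {
  expect_equal(compute_delta_te(2, 1)$delta_te, 2)
  expect_equal(compute_delta_te(2, 1)$log2_delta_te, 1)
  expect_equal(compute_delta_te(1, 1)$log2_delta_te, 0)
  expect_equal(compute_delta_te(0.5, 2)$delta_te, 0.25)
  expect_equal(compute_delta_te(0.5, 2)$log2_delta_te, -2)
  # geometric mean over replicates
  expect_equal(compute_delta_te(c(1, 4), c(1, 1))$delta_te, 2)
  expect_error(compute_delta_te(c(1, -1), 1), "positive")
})

test_that("TE change test behaves at degenerate and oracle-checkable inputs", {
  expect_warning(p1 <- test_te_change(1, c(1, 2)), "replicates")
  expect_equal(p1, 1)
  expect_equal(test_te_change(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-9)

  # separated groups with zero within-group variance: epsilon floor keeps
  # the statistic finite and extreme
  p <- test_te_change(c(0, 0, 0), c(2, 2, 2))
  expect_lt(p, 0.01)
  # the exact permutation p for the same data is 2/20 (only the two
  # un-mixed relabelings reach the observed separation)
  expect_equal(test_te_change(c(0, 0, 0), c(2, 2, 2), mode = "permutation"),
               2 / 20)

  # parametric p tracks the exact permutation p at 3+3 distinct values;
  # the permutation null at 3+3 is granular (atoms at multiples of 1/20,
  # none below 0.1), so close agreement is a majority property, not a
  # pointwise bound
  set.seed(7)
  diffs <- replicate(50, {
    x <- rnorm(3); y <- rnorm(3, mean = sample(c(0, 1.5), 1))
    abs(test_te_change(x, y) -
          test_te_change(x, y, mode = "permutation"))
  })
  expect_gte(mean(diffs < 0.15), 0.9)
  expect_lt(max(diffs), 0.4)
  expect_error(test_te_change(rnorm(6), rnorm(6), mode = "permutation"),
               "at most 10")
})

test_that("TE classification applies both the fold-change and p gates", {
  thr <- analysis_thresholds(alpha = 0.05, log2fc_cut = 1)
  expect_identical(classify_te(2, 0.001, thr), "up")
  expect_identical(classify_te(-2, 0.001, thr), "down")
  expect_identical(classify_te(0, 0.001, thr), "insensitive")
  expect_identical(classify_te(2, 0.5, thr), "insensitive")
  expect_identical(classify_te(c(1, -1), c(0.05, 0.05), thr),
                   c("up", "down"))
  expect_identical(classify_te(NA, 0.01, thr), NA_character_)
})

test_that("nine-quadrant labels trichotomise both axes with the gates", {
  thr <- analysis_thresholds()
  expect_identical(nine_quadrant(0, 2, 1, 0.001, thr), "rna-flat_ribo-up")
  expect_identical(nine_quadrant(2, 2, 0.001, 0.001, thr), "rna-up_ribo-up")
  expect_identical(nine_quadrant(0, 0, 0.5, 0.5, thr), "rna-flat_ribo-flat")
  # significance gate: large fold change without significance stays flat
  expect_identical(nine_quadrant(2, -2, 0.5, 0.5, thr), "rna-flat_ribo-flat")
  expect_true(translatome_only("rna-flat_ribo-down"))
  expect_false(translatome_only("rna-up_ribo-up"))

  # partition over a grid: every label is one of the 9, each gene gets one
  grid <- expand.grid(r = c(-2, 0, 2), b = c(-2, 0, 2))
  labs <- nine_quadrant(grid$r, grid$b, rep(0.001, 9), rep(0.001, 9), thr)
  all9 <- as.vector(outer(c("rna-down", "rna-flat", "rna-up"),
                          c("ribo-down", "ribo-flat", "ribo-up"), paste,
                          sep = "_"))
  expect_setequal(labs, all9)
})

test_that("the analysis table partitions analysed genes exhaustively", {
  fx <- small_te_fixture()
  te <- fx$te
  analysed <- !te$excluded
  expect_true(all(te$te_class[analysed] %in% c("up", "down", "insensitive")))
  expect_true(all(grepl("^rna-(down|flat|up)_ribo-(down|flat|up)$",
                        te$quadrant[analysed])))
  expect_true(all(is.na(te$te_class[!analysed])))
  expect_equal(te$delta_te, te$te_treat / te$te_ctrl)
  expect_equal(te$log2_delta_te, log2(te$delta_te))
  expect_true(all(te$fdr[analysed] >= te$p[analysed] - 1e-12))
})

test_that("TE is invariant to rescaling a sample's library", {
  fx <- small_te_fixture()
  rpf2 <- fx$rpf
  rpf2$counts[, 1] <- rpf2$counts[, 1] * 3L
  fpkm_rpf2 <- compute_fpkm(rpf2, effective_lengths(fx$models, "RPF"))
  te2 <- te_analysis(fpkm_rpf2, fx$fpkm_rna)
  expect_equal(te2$delta_te, fx$te$delta_te)
  expect_equal(te2$p, fx$te$p)
  expect_identical(te2$te_class, fx$te$te_class)
  expect_identical(te2$quadrant, fx$te$quadrant)
})

test_that("swapping condition labels inverts delta-TE and the classes", {
  fx <- small_te_fixture()
  fpkm_rna_sw <- compute_fpkm(swap_conditions(fx$rna),
                              effective_lengths(fx$models, "RNA"))
  fpkm_rpf_sw <- compute_fpkm(swap_conditions(fx$rpf),
                              effective_lengths(fx$models, "RPF"))
  te_sw <- te_analysis(fpkm_rpf_sw, fpkm_rna_sw)
  expect_equal(te_sw$delta_te, 1 / fx$te$delta_te)
  expect_equal(te_sw$log2_delta_te, -fx$te$log2_delta_te)
  expect_equal(te_sw$p, fx$te$p)
  map <- c(up = "down", down = "up", insensitive = "insensitive")
  expect_identical(te_sw$te_class, unname(map[fx$te$te_class]))
})
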