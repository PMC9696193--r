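test_that("GC percent counts G+C and treats empty sequences as missing", {
  expect_equal(gc_percent("AUGC"), 50)
  expect_equal(gc_percent("AAAA"), 0)
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("atgc"), 50)  # case and T-as-U tolerated
  expect_true(is.na(gc_percent("")))
  expect_true(is.na(gc_percent(NA_character_)))
  # GC is preserved under reverse complementation (A<->U, G<->C)
  set.seed(3)
  for (i in 1:20) {
    s <- random_rna(sample(5:60, 1))
    expect_equal(gc_percent(reverse_complement(s)), gc_percent(s))
  }
})

test_that("folding returns the enumerated optimum on small sequences", {
  expect_equal(mfe_fold("AAAAAA")$energy, 0)
  expect_equal(nrow(mfe_fold("AAAAAA")$pairs), 0)
  expect_equal(mfe_fold("GCGC")$energy, 0)  # too short for any loop
  f <- mfe_fold("GGGAAACCC")
  expect_equal(f$energy, -9)
  expect_equal(f$structure, "(((...)))")
  expect_error(mfe_fold("GGXCC"), "position 3")
  expect_error(mfe_fold("AAA", energies = c(GC = 1, AU = -2, GU = -1)),
               "negative")

  set.seed(11)
  for (i in 1:40) {
    s <- random_rna(sample(4:12, 1))
    expect_equal(fold_energy(s), oracle_min_energy(s), info = s)
  }
})

test_that("every traceback is a valid nested structure achieving the optimum", {
  set.seed(19)
  energies <- c(GC = -3, AU = -2, GU = -1)
  for (i in 1:25) {
    s <- random_rna(sample(10:40, 1))
    f <- mfe_fold(s)
    expect_true(structure_is_valid(s, f$pairs), info = s)
    bases <- strsplit(s, "", fixed = TRUE)[[1]]
    esum <- if (nrow(f$pairs) == 0L) 0 else
      sum(apply(f$pairs, 1, function(p)
        oracle_pair_energy(bases[p[1]], bases[p[2]], energies)))
    expect_equal(esum, f$energy, info = s)
    expect_lte(f$energy, 0)
  }
})

test_that("uORF census counts AUG starts closed by in-frame stops", {
  expect_equal(find_uorfs("AUGAAAUAA"), 1L)
  expect_equal(find_uorfs("AAAAAA"), 0L)
  expect_equal(find_uorfs("AUGAUGUAAUAA"), 2L)
  expect_equal(find_uorfs(""), 0L)
  # an AUG without an in-frame stop is open into the CDS
  expect_equal(find_uorfs("AUGAAA"), 0L)
  expect_equal(find_uorfs("AUGAAA", include_open = TRUE), 1L)
  # appending downstream of the last stop never removes a uORF
  set.seed(23)
  for (i in 1:15) {
    s <- random_rna(sample(10:50, 1))
    expect_gte(find_uorfs(paste0(s, random_rna(9))), find_uorfs(s))
  }
})

test_that("rank-sum test matches enumeration, with midranks and symmetry", {
  rs <- rank_sum_test(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(rs$u_statistic, 0)
  expect_equal(rs$p_value, 2 / 6)
  # complete exchangeability
  expect_equal(rank_sum_test(c(5, 1, 3), c(3, 5, 1), mode = "exact")$p_value,
               1)
  expect_equal(rank_sum_test(rep(2, 4), rep(2, 3))$p_value, 1)

  set.seed(29)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    pool <- sample(1:6, n1 + n2, replace = TRUE)  # ties likely
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    ex <- rank_sum_test(x, y, mode = "exact")
    expect_equal(ex$p_value, oracle_ranksum_p(x, y), tolerance = 1e-12)
    # U range and swap symmetry
    sw <- rank_sum_test(y, x, mode = "exact")
    expect_equal(sw$u_statistic, n1 * n2 - ex$u_statistic)
    expect_equal(sw$p_value, ex$p_value)
    expect_true(ex$u_statistic >= 0 && ex$u_statistic <= n1 * n2)
  }

  # tie-free exact p agrees with the independent implementation in stats
  set.seed(31)
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(rank_sum_test(x, y, mode = "exact")$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("feature table covers all regions and comparisons find the plant", {
  models <- data.frame(gene_id = c("a", "b"),
                       utr5 = c("GGGAAACCC", ""),
                       cds = c("AUGGCGUAA", "AUGUAA"),
                       utr3 = c("AAUU", ""), stringsAsFactors = FALSE)
  ft <- feature_table(models)
  expect_equal(ft$gc5, c(gc_percent("GGGAAACCC"), NA))
  expect_equal(ft$len5, c(9L, 0L))
  expect_equal(ft$len_cds, c(9L, 6L))
  expect_equal(ft$dG5, c(-9, NA))
  expect_equal(ft$dG5_per_nt, c(-1, NA))
  expect_equal(ft$n_uorf, c(0L, 0L))

  # identical feature values in every class give p = 1 throughout
  flat <- data.frame(gene_id = sprintf("g%02d", 1:30), gc5 = 50, len5 = 100,
                     dG5 = -20, len3 = 200, len_cds = 300, n_uorf = 1)
  cls <- data.frame(gene_id = flat$gene_id,
                    te_class = rep(c("up", "down", "insensitive"), each = 10))
  cmp <- compare_feature_distributions(flat, cls)
  expect_true(all(cmp$p_value == 1))
  expect_equal(nrow(cmp), 12)

  # undersized classes are skipped with a warning
  cls2 <- cls
  cls2$te_class[cls2$te_class == "up"] <- "insensitive"
  cls2$te_class[1:2] <- "up"
  expect_warning(compare_feature_distributions(flat, cls2,
                                               feature_cols = "gc5"),
                 "fewer than")
  cmp2 <- suppressWarnings(compare_feature_distributions(flat, cls2))
  expect_true(all(cmp2$group_a == "down"))
})
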