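# 5'UTR/CDS/3'UTR feature statistics: GC%, lengths, Nussinov folding
# energy, uORF census, Mann-Whitney group comparisons.

#' GC content of a sequence
#'
#' 100 * (#G + #C) / length.  Empty or missing sequences are reported as
#' `NA` (missing), never as 0.
#'
#' @param seq character vector of nucleotide sequences (T accepted as U).
#' @return numeric vector of percentages in [0, 100].
#' @export
gc_percent <- function(seq) {
  out <- rep(NA_real_, length(seq))
  ok <- !is.na(seq) & nzchar(seq)
  if (any(ok)) {
    s <- as_rna(seq[ok])
    n_gc <- nchar(gsub("[^GC]", "", s))
    out[ok] <- 100 * n_gc / nchar(s)
  }
  out
}

#' Minimum-energy nested RNA secondary structure (Nussinov-style)
#'
#' Dynamic program minimising the summed energies of Watson-Crick and
#' wobble pairs (defaults G:C = -3, A:U = -2, G:U = -1) over all
#' pseudoknot-free structures with hairpin loops of at least `min_loop`
#' unpaired bases.  This is a self-contained base-pair maximisation model
#' with weighted pairs, not a nearest-neighbour thermodynamic model; its
#' energies are "kcal/mol-like" model units that rank structural
#' complexity.  Users needing physical free energies can substitute any
#' external folder's values into [feature_table()] via its `dG5` column.
#'
#' @param seq a single sequence over {A, C, G, U} (T accepted as U).
#' @param energies named numeric: `GC`, `AU`, `GU` pair energies (< 0).
#' @param min_loop minimum hairpin loop length (unpaired bases).
#' @return list of class `secondary_structure`: `energy` (<= 0), `pairs`
#'   (two-column matrix of 1-based i < j positions) and `structure`
#'   (dot-bracket string).
#' @export
mfe_fold <- function(seq, energies = c(GC = -3, AU = -2, GU = -1),
                     min_loop = 3) {
  stopifnot(length(seq) == 1L)
  s <- as_rna(seq)
  if (any(energies >= 0)) stop("pair energies must be negative", call. = FALSE)
  res <- nussinov_fold_cpp(s, energies[["GC"]], energies[["AU"]],
                           energies[["GU"]], as.integer(min_loop), TRUE)
  pairs <- res$pairs
  db <- rep(".", nchar(s))
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  structure(list(energy = res$energy, pairs = pairs,
                 structure = paste(db, collapse = "")),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> energy %g, %d pairs\n%s\n",
              x$energy, nrow(x$pairs), x$structure))
  invisible(x)
}

#' Folding energies for many sequences
#'
#' Vectorised energy-only version of [mfe_fold()].  Empty sequences give
#' `NA`.
#'
#' @inheritParams mfe_fold
#' @param seqs character vector of sequences.
#' @return numeric vector of minimum energies (<= 0).
#' @export
fold_energy <- function(seqs, energies = c(GC = -3, AU = -2, GU = -1),
                        min_loop = 3) {
  out <- rep(NA_real_, length(seqs))
  ok <- !is.na(seqs) & nzchar(seqs)
  if (any(ok))
    out[ok] <- nussinov_energy_cpp(as_rna(seqs[ok]), energies[["GC"]],
                                   energies[["AU"]], energies[["GU"]],
                                   as.integer(min_loop))
  out
}

#' Count upstream open reading frames in a 5'UTR
#'
#' A uORF is an AUG inside the 5'UTR whose first in-frame stop codon
#' (UAA/UAG/UGA) also lies fully inside the 5'UTR.  Overlapping and nested
#' uORFs are counted separately, one per start codon.  AUGs with no
#' in-frame stop before the UTR ends (uORFs open into the CDS) are not
#' counted unless `include_open = TRUE`.
#'
#' @param utr5_seq character vector of 5'UTR sequences (may be empty).
#' @param include_open also count AUGs lacking an in-frame stop in the UTR.
#' @return integer vector of uORF counts.
#' @export
find_uorfs <- function(utr5_seq, include_open = FALSE) {
  stops <- c("UAA", "UAG", "UGA")
  vapply(utr5_seq, function(s) {
    if (is.na(s) || !nzchar(s)) return(0L)
    s <- as_rna(s)
    n <- nchar(s)
    count <- 0L
    starts <- which(vapply(seq_len(max(n - 2L, 0L)), function(i)
      substr(s, i, i + 2L) == "AUG", logical(1)))
    for (i in starts) {
      pos <- i + 3L
      closed <- FALSE
      while (pos + 2L <= n) {
        if (substr(s, pos, pos + 2L) %in% stops) {
          closed <- TRUE
          break
        }
        pos <- pos + 3L
      }
      if (closed || include_open) count <- count + 1L
    }
    count
  }, integer(1), USE.NAMES = FALSE)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided rank-sum test with midranks for ties.  `mode = "exact"`
#' enumerates all C(n_a + n_b, n_a) group labelings (permitted for up to
#' 12 total observations); `mode = "normal"` uses the normal approximation
#' with continuity correction and tie-corrected variance.  When every
#' value in both groups is identical the p-value is 1.
#'
#' @param x,y numeric samples for the two groups.
#' @param mode `"normal"` or `"exact"`.
#' @return list of class `rank_sum`: `u_statistic` (U of the first
#'   group, in [0, n_a*n_b]), `p_value`, `n_a`, `n_b`, `mode`.
#' @export
rank_sum_test <- function(x, y, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  }
  U <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2

  if (length(unique(pooled)) == 1L) {
    p <- 1
  } else if (mode == "exact") {
    if (n1 + n2 > 12L)
      stop("exact mode supports at most 12 total observations", call. = FALSE)
    labelings <- combn(n1 + n2, n1)
    r <- rank(pooled)
    us <- colSums(matrix(r[labelings], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, mean(abs(us - mu) >= abs(U - mu) - 1e-12))
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * pnorm(-z))
  }
  structure(list(u_statistic = U, p_value = p, n_a = n1, n_b = n2,
                 mode = mode),
            class = "rank_sum")
}

#' @export
print.rank_sum <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$u_statistic, x$n_a, x$n_b, x$p_value, x$mode))
  invisible(x)
}

#' Per-gene sequence feature table
#'
#' Computes, for every transcript model: 5'UTR GC% (`gc5`), region lengths
#' (`len5`, `len_cds`, `len3`), 5'UTR folding energy (`dG5`, Nussinov
#' model units, plus the length-normalised `dG5_per_nt`) and the uORF
#' count (`n_uorf`).
#'
#' @param models transcript models data.frame (columns `gene_id`, `utr5`,
#'   `cds`, `utr3`).
#' @param energies,min_loop folding model, see [mfe_fold()].
#' @param include_open_uorfs count CDS-overlapping uORFs, see
#'   [find_uorfs()].
#' @return data.frame, one row per gene.
#' @export
feature_table <- function(models, energies = c(GC = -3, AU = -2, GU = -1),
                          min_loop = 3, include_open_uorfs = FALSE) {
  utr5 <- models$utr5
  dG5 <- fold_energy(utr5, energies, min_loop)
  len5 <- nchar(utr5)
  data.frame(gene_id = models$gene_id,
             gc5 = gc_percent(utr5),
             len5 = len5,
             len_cds = nchar(models$cds),
             len3 = nchar(models$utr3),
             dG5 = dG5,
             dG5_per_nt = ifelse(len5 > 0, dG5 / len5, NA_real_),
             n_uorf = find_uorfs(utr5, include_open = include_open_uorfs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare feature distributions between TE classes
#'
#' For each feature, tests TE-up vs TE-insensitive and TE-down vs
#' TE-insensitive with the Mann-Whitney rank-sum test (normal
#' approximation).  Comparisons where either class has fewer than `min_n`
#' genes are skipped with a warning.
#'
#' @param features a [feature_table()].
#' @param te_table a [te_analysis()] table (columns `gene_id`,
#'   `te_class`).
#' @param feature_cols which feature columns to compare.
#' @param min_n minimum class size.
#' @return data.frame: `feature`, `group_a`, `group_b`, `u_statistic`,
#'   `p_value`, `n_a`, `n_b`.
#' @export
compare_feature_distributions <- function(features, te_table,
                                          feature_cols = c("gc5", "len5",
                                                           "dG5", "len3",
                                                           "len_cds",
                                                           "n_uorf"),
                                          min_n = 3) {
  common <- intersect(features$gene_id, te_table$gene_id)
  if (length(common) == 0L)
    stop("feature and TE tables share no genes", call. = FALSE)
  cls <- te_table$te_class[match(common, te_table$gene_id)]
  feat <- features[match(common, features$gene_id), , drop = FALSE]

  rows <- list()
  for (fc in feature_cols) {
    for (grp in c("up", "down")) {
      xa <- feat[[fc]][!is.na(cls) & cls == grp]
      xb <- feat[[fc]][!is.na(cls) & cls == "insensitive"]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (length(xa) < min_n || length(xb) < min_n) {
        warning("skipping ", fc, " ", grp, " vs insensitive: fewer than ",
                min_n, " genes in a class")
        next
      }
      rs <- rank_sum_test(xa, xb, mode = "normal")
      rows[[length(rows) + 1L]] <-
        data.frame(feature = fc, group_a = grp, group_b = "insensitive",
                   u_statistic = rs$u_statistic, p_value = rs$p_value,
                   n_a = rs$n_a, n_b = rs$n_b, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(feature = character(0), group_a = character(0),
                      group_b = character(0), u_statistic = numeric(0),
                      p_value = numeric(0), n_a = integer(0),
                      n_b = integer(0)))
  do.call(rbind, rows)
}
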