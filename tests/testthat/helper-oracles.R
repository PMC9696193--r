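# Independent brute-force oracles used to validate the package's dynamic
# programs and tail probabilities on small instances.

# energy of a single base pair under the weighted pair model; NA = cannot pair
oracle_pair_energy <- function(a, b, energies) {
  key <- paste(sort(c(a, b)), collapse = "")
  switch(key,
         "CG" = energies[["GC"]],
         "AU" = energies[["AU"]],
         "GU" = energies[["GU"]],
         NA_real_)
}

# enumerate every pseudoknot-free structure on bases[i..j] (hairpin loops of
# at least min_loop unpaired bases) as a list of pair matrices.  Each
# structure is produced exactly once by deciding the fate of position i.
oracle_enumerate_structures <- function(bases, min_loop = 3,
                                        energies = c(GC = -3, AU = -2,
                                                     GU = -1)) {
  recurse <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), ncol = 2)))
    out <- lapply(recurse(i + 1, j), identity)  # i unpaired
    ks <- seq_len(j)
    ks <- ks[ks >= i + min_loop + 1]
    for (k in ks) {
      if (is.na(oracle_pair_energy(bases[i], bases[k], energies))) next
      inner <- recurse(i + 1, k - 1)
      outer <- recurse(k + 1, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    out
  }
  recurse(1, length(bases))
}

# exhaustive minimum over all enumerated structures
oracle_min_energy <- function(seq, min_loop = 3,
                              energies = c(GC = -3, AU = -2, GU = -1)) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  structs <- oracle_enumerate_structures(bases, min_loop, energies)
  vals <- vapply(structs, function(s) {
    if (nrow(s) == 0L) return(0)
    sum(vapply(seq_len(nrow(s)), function(r)
      oracle_pair_energy(bases[s[r, 1]], bases[s[r, 2]], energies),
      numeric(1)))
  }, numeric(1))
  min(vals)
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  U_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  labelings <- combn(n1 + n2, n1)
  us <- apply(labelings, 2, u_of)
  if (length(unique(pooled)) == 1L) return(1)
  min(1, mean(abs(us - mu) >= abs(U_obs - mu) - 1e-12))
}

# upper-tail hypergeometric probability by direct combinatorial summation
oracle_hyper_p <- function(k, K, n, N) {
  if (k == 0) return(1)
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# random RNA sequence
random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# check a traceback structure for nesting / loop / pair-type validity
structure_is_valid <- function(seq, pairs, min_loop = 3) {
  if (nrow(pairs) == 0L) return(TRUE)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok_pairs <- all(apply(pairs, 1, function(p) {
    !is.na(oracle_pair_energy(bases[p[1]], bases[p[2]],
                              c(GC = -3, AU = -2, GU = -1)))
  }))
  ok_loop <- all(pairs[, 2] - pairs[, 1] > min_loop)
  positions <- c(pairs)
  ok_disjoint <- !anyDuplicated(positions)
  # nesting: no two pairs (i,j), (k,l) with i < k < j < l
  ok_nested <- TRUE
  if (nrow(pairs) > 1L) {
    for (a in seq_len(nrow(pairs) - 1L)) {
      for (b in (a + 1L):nrow(pairs)) {
        i <- pairs[a, 1]; j <- pairs[a, 2]
        k <- pairs[b, 1]; l <- pairs[b, 2]
        crossing <- (i < k & k < j & j < l) | (k < i & i < l & l < j)
        if (crossing) ok_nested <- FALSE
      }
    }
  }
  ok_pairs && ok_loop && ok_disjoint && ok_nested
}
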