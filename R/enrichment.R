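# Hypergeometric over-representation analysis against GMT gene sets.

#' Upper-tail hypergeometric probability
#'
#' P[X >= k] for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` members of a size-`K` set when sampling `n` genes without
#' replacement from a universe of `N`.  Computed by summing the pmf in log
#' space for numerical stability at extreme tails.
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || k > min(K, n) || K > N || n > N)
    stop("invalid hypergeometric parameters: k=", k, " K=", K, " n=", n,
         " N=", N, call. = FALSE)
  if (k == 0) return(1)
  x <- k:min(K, n)
  logp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, fields tab-separated — name,
#' description, then member gene ids.
#'
#' @param path GMT file path.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in ", path, call. = FALSE)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query genes within
#' the universe.  Set members and query genes outside the universe are
#' trimmed (with a warning); sets whose trimmed size falls outside
#' `[min_set, max_set]` are dropped.  Rows are sorted by p-value and
#' carry Benjamini-Hochberg FDR across the retained sets.
#'
#' @param query gene ids of interest (e.g. the TE-sensitive genes).
#' @param sets named list of gene-id vectors (see [read_gmt()]).
#' @param universe background gene ids; conventionally the analysed
#'   (detection-filtered) genes, not the whole annotation.
#' @param min_set,max_set retained set-size range.
#' @return data.frame: `set`, `k` (overlap), `K` (set size), `n` (query
#'   size), `N` (universe size), `p_value`, `fdr`, `genes`
#'   (comma-separated overlap).
#' @export
enrich <- function(query, sets, universe, min_set = 5, max_set = 500) {
  universe <- unique(universe)
  N <- length(universe)
  dropped <- setdiff(query, universe)
  if (length(dropped))
    warning(length(dropped), " query gene(s) outside the universe trimmed")
  query <- unique(intersect(query, universe))
  n <- length(query)
  empty <- data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      fdr = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    warning("empty query after trimming to the universe")
    return(empty)
  }
  trimmed <- lapply(sets, intersect, universe)
  keep <- vapply(trimmed, function(s)
    length(s) >= min_set && length(s) <= max_set, logical(1))
  trimmed <- trimmed[keep]
  if (length(trimmed) == 0L) return(empty)

  rows <- lapply(names(trimmed), function(nm) {
    members <- trimmed[[nm]]
    hit <- intersect(query, members)
    data.frame(set = nm, k = length(hit), K = length(members), n = n, N = N,
               p_value = hypergeometric_p(length(hit), length(members), n, N),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set),
             c("set", "k", "K", "n", "N", "p_value", "fdr", "genes")]
  rownames(out) <- NULL
  out
}
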