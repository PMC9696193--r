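# Shared low-level helpers: alphabet handling, TSV io, small checks.

#' Normalise a nucleotide sequence to the RNA alphabet
#'
#' Uppercases and converts T to U. Sequences are validated against
#' {A, C, G, U}; the position of the first offending character is reported.
#'
#' @param seq character vector of sequences (DNA or RNA alphabet).
#' @return character vector over {A, C, G, U}.
#' @export
as_rna <- function(seq) {
  out <- chartr("t", "u", toupper(seq))
  out <- chartr("T", "U", out)
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0L, na.rm = TRUE)) {
    i <- which(bad > 0L)[1L]
    stop("invalid character '", substr(out[i], bad[i], bad[i]),
         "' at position ", bad[i], " of sequence ", i, call. = FALSE)
  }
  out
}

#' Reverse complement over the RNA alphabet
#'
#' Complements with A-U and G-C pairing (T accepted as U) and reverses.
#'
#' @param seq character vector.
#' @return character vector of reverse complements (RNA alphabet).
#' @export
reverse_complement <- function(seq) {
  seq <- as_rna(seq)
  comp <- chartr("ACGU", "UGCA", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

# write a data.frame as TSV with a header; NA encoded as "NA"
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

# read a TSV with header; reject files missing required columns by name
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L)
      stop("file ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(name, " must be a single number in [", lo, ", ", hi, "]",
         call. = FALSE)
  invisible(x)
}
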