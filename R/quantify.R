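# FPKM quantification: RPF length filtering and count-to-FPKM conversion.

#' Filter ribosome-protected fragment lengths to an analysis window
#'
#' Returns the indices of fragments whose length falls inside the closed
#' window, preserving order.  The conventional Ribo-seq analysis window is
#' 28-30 nt within the 26-32 nt RPF size range.
#'
#' @param lengths integer vector of fragment lengths.
#' @param window numeric `c(lo, hi)` closed interval.
#' @return integer indices of the kept fragments.
#' @export
filter_rpf_lengths <- function(lengths, window = c(28, 30)) {
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be c(lo, hi) with lo <= hi", call. = FALSE)
  which(lengths >= window[1] & lengths <= window[2])
}

#' Convert counts to FPKM
#'
#' FPKM = C / ((L / 1000) * (N / 1e6)): fragments per kilobase of effective
#' gene length per million library fragments.  For RPF libraries the
#' effective length is conventionally the CDS length (ribosomes occupy the
#' coding region); for RNA libraries the full transcript length (see
#' [effective_lengths()]).
#'
#' @param counts a [count_matrix()].
#' @param effective_length_nt named numeric vector, gene -> effective
#'   length in nucleotides (> 0), covering every gene in `counts`.
#' @param library_size optional named numeric vector, sample -> library
#'   size (> 0); defaults to each sample's column sum.
#' @return object of class `expression_table`: list with `fpkm` matrix
#'   (genes x samples), `effective_length_nt`, `library_size`, `assay` and
#'   the `samples` sheet.
#' @export
compute_fpkm <- function(counts, effective_length_nt, library_size = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  genes <- rownames(counts$counts)
  missing <- setdiff(genes, names(effective_length_nt))
  if (length(missing))
    stop("no effective length for gene(s): ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  len <- effective_length_nt[genes]
  bad <- len <= 0 | !is.finite(len)
  if (any(bad))
    stop("non-positive effective length for gene(s): ",
         paste(head(genes[bad], 10), collapse = ", "), call. = FALSE)
  if (is.null(library_size)) {
    library_size <- colSums(counts$counts)
  } else {
    miss <- setdiff(colnames(counts$counts), names(library_size))
    if (length(miss))
      stop("no library size for sample(s): ",
           paste(head(miss, 10), collapse = ", "), call. = FALSE)
    library_size <- library_size[colnames(counts$counts)]
  }
  bad <- library_size <= 0 | !is.finite(library_size)
  if (any(bad))
    stop("non-positive library size for sample(s): ",
         paste(head(names(library_size)[bad], 10), collapse = ", "),
         call. = FALSE)
  fpkm <- sweep(counts$counts / (len / 1000), 2, library_size / 1e6, "/")
  structure(list(fpkm = fpkm, effective_length_nt = len,
                 library_size = library_size, assay = counts$assay,
                 samples = counts$samples),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %s assay: %d genes x %d samples\n",
              x$assay, nrow(x$fpkm), ncol(x$fpkm)))
  invisible(x)
}

#' Effective gene lengths for FPKM
#'
#' RNA-seq libraries sample the whole transcript, so the effective length
#' is 5'UTR + CDS + 3'UTR; Ribo-seq fragments come from translating
#' ribosomes, so the CDS length is used.  The choice is exposed so either
#' denominator can be applied to either assay.
#'
#' @param models transcript models data.frame (columns `gene_id`, `utr5`,
#'   `cds`, `utr3`).
#' @param assay `"RNA"` (transcript length) or `"RPF"` (CDS length).
#' @return named numeric vector of lengths in nucleotides.
#' @export
effective_lengths <- function(models, assay = c("RNA", "RPF")) {
  assay <- match.arg(assay)
  len <- if (assay == "RNA")
    nchar(models$utr5) + nchar(models$cds) + nchar(models$utr3)
  else nchar(models$cds)
  names(len) <- models$gene_id
  len
}
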