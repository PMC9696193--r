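# File formats: FASTA, GTF-subset annotation, and the pipeline's TSV
# schemas (counts, sample sheet, ground truth, TE/feature/enrichment
# tables).

#' Read a FASTA file into a named character vector
#'
#' Record order is preserved, sequences are uppercased, and the id is the
#' first whitespace-delimited token of each header.  Duplicate ids are an
#' error; an empty file yields an empty mapping with a warning.  Alphabet
#' validation is left to each downstream consumer (via [as_rna()]).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  setNames(toupper(as.character(seqs)), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nzchar(s)) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
                 con)
    }
  }
  invisible(path)
}

#' Convert transcript models to region-suffixed FASTA records
#'
#' Ids are `<gene>|5utr`, `<gene>|cds`, `<gene>|3utr`; empty regions are
#' written as empty records so the round trip is lossless.
#'
#' @param models transcript models data.frame.
#' @return named character vector suitable for [write_fasta()].
#' @export
models_to_fasta <- function(models) {
  ids <- c(rbind(paste0(models$gene_id, "|5utr"),
                 paste0(models$gene_id, "|cds"),
                 paste0(models$gene_id, "|3utr")))
  setNames(c(rbind(models$utr5, models$cds, models$utr3)), ids)
}

#' Reassemble transcript models from region-suffixed FASTA records
#'
#' @param seqs named character vector with ids `<gene>|{5utr,cds,3utr}`.
#' @return transcript models data.frame (`gene_id`, `strand`, `utr5`,
#'   `cds`, `utr3`), RNA alphabet.
#' @export
fasta_to_models <- function(seqs) {
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(parts) != 2L |
    !vapply(parts, function(p) p[2] %in% c("5utr", "cds", "3utr"), logical(1))
  if (any(bad))
    stop("FASTA id(s) not of the form <gene>|{5utr,cds,3utr}: ",
         paste(head(names(seqs)[bad], 10), collapse = ", "), call. = FALSE)
  gene <- vapply(parts, `[`, character(1), 1L)
  region <- vapply(parts, `[`, character(1), 2L)
  genes <- unique(gene)
  grab <- function(g, r) {
    i <- which(gene == g & region == r)
    if (length(i) == 0L) "" else as_rna(seqs[[i]])
  }
  data.frame(gene_id = genes, strand = "+",
             utr5 = vapply(genes, grab, character(1), r = "5utr"),
             cds = vapply(genes, grab, character(1), r = "cds"),
             utr3 = vapply(genes, grab, character(1), r = "3utr"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a GTF-subset annotation for transcript models
#'
#' One synthetic reference sequence per gene (seqname = gene id), 1-based
#' inclusive coordinates, features `five_prime_utr`, `CDS`,
#' `three_prime_utr` in transcript order on the plus strand.
#'
#' @param models transcript models data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_annotation <- function(models, path) {
  rows <- list()
  for (i in seq_len(nrow(models))) {
    g <- models$gene_id[i]
    lens <- c(five_prime_utr = nchar(models$utr5[i]),
              CDS = nchar(models$cds[i]),
              three_prime_utr = nchar(models$utr3[i]))
    pos <- 1L
    for (feat in names(lens)) {
      if (lens[[feat]] == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        seqname = g, source = "riboTE", feature = feat, start = pos,
        end = pos + lens[[feat]] - 1L, score = ".", strand = "+",
        frame = ".", attributes = sprintf('gene_id "%s";', g),
        stringsAsFactors = FALSE)
      pos <- pos + lens[[feat]]
    }
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a GTF-subset annotation into transcript models
#'
#' Accepts the three features `five_prime_utr`, `CDS` and
#' `three_prime_utr` with 1-based inclusive coordinates; unknown feature
#' types are skipped (their count is reported).  Multi-record features are
#' concatenated in genomic order; minus-strand genes are
#' reverse-complemented, so the returned regions are in transcript
#' orientation.  Overlapping same-feature records for one gene are an
#' error, as are coordinates outside the reference.
#'
#' @param path GTF-subset file.
#' @param reference named character vector of reference sequences (from
#'   [read_fasta()]).
#' @return transcript models data.frame (`gene_id`, `strand`, `utr5`,
#'   `cds`, `utr3`), RNA alphabet.
#' @export
read_annotation <- function(path, reference) {
  gtf <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, quote = "",
                    col.names = c("seqname", "source", "feature", "start",
                                  "end", "score", "strand", "frame",
                                  "attributes"))
  known <- c("five_prime_utr", "CDS", "three_prime_utr")
  unknown <- !(gtf$feature %in% known)
  if (any(unknown)) {
    message("skipping ", sum(unknown), " record(s) with unknown feature type")
    gtf <- gtf[!unknown, , drop = FALSE]
  }
  gene <- sub('.*gene_id "([^"]+)".*', "\\1", gtf$attributes)

  extract <- function(rows) {
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) > 1L && any(rows$start[-1] <= rows$end[-nrow(rows)]))
      stop("overlapping records for feature ", rows$feature[1], " of gene ",
           rows$gid[1], call. = FALSE)
    pieces <- character(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      ref <- unname(reference[rows$seqname[r]])
      if (length(ref) != 1L || is.na(ref))
        stop("reference sequence not found: ", rows$seqname[r],
             call. = FALSE)
      if (rows$start[r] < 1L || rows$end[r] > nchar(ref) ||
          rows$start[r] > rows$end[r])
        stop("coordinates out of bounds for gene ", rows$gid[1], ": ",
             rows$start[r], "-", rows$end[r], call. = FALSE)
      pieces[r] <- substr(ref, rows$start[r], rows$end[r])
    }
    seq <- paste(pieces, collapse = "")
    if (rows$strand[1] == "-") reverse_complement(seq) else as_rna(seq)
  }

  gtf$gid <- gene
  out <- lapply(unique(gene), function(g) {
    sub <- gtf[gene == g, , drop = FALSE]
    strand <- sub$strand[1]
    get <- function(feat) {
      rows <- sub[sub$feature == feat, , drop = FALSE]
      if (nrow(rows) == 0L) "" else extract(rows)
    }
    data.frame(gene_id = g, strand = strand,
               utr5 = get("five_prime_utr"), cds = get("CDS"),
               utr3 = get("three_prime_utr"), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Write a count matrix as TSV
#'
#' Header `gene_id<TAB>sample...`, one row per gene.
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_counts_tsv <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a count matrix TSV plus sample sheet
#'
#' @param path counts TSV written by [write_counts_tsv()].
#' @param samples sample sheet data.frame (or path to a TSV with columns
#'   `sample_id`, `condition`, `assay`, `replicate`).
#' @param assay which assay's samples to select from the sheet.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path, samples, assay = c("RNA", "RPF")) {
  assay <- match.arg(assay)
  df <- read_tsv(path, required = "gene_id")
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  sheet <- samples[samples$assay == assay, , drop = FALSE]
  missing <- setdiff(sheet$sample_id, names(df))
  if (length(missing))
    stop("counts file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, sheet$sample_id, drop = FALSE])
  rownames(m) <- df$gene_id
  count_matrix(m, assay, sheet)
}

#' Read a sample sheet TSV
#'
#' @param path TSV with columns `sample_id`, `condition`, `assay`,
#'   `replicate`.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  read_tsv(path, required = c("sample_id", "condition", "assay",
                              "replicate"))
}

#' Write an expression (FPKM) table as TSV
#'
#' Values are written with 6 significant digits.
#'
#' @param et an [compute_fpkm()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fpkm_tsv <- function(et, path) {
  df <- data.frame(gene_id = rownames(et$fpkm),
                   effective_length_nt = et$effective_length_nt,
                   signif(et$fpkm, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an FPKM TSV back into an expression table
#'
#' Inverse of [write_fpkm_tsv()] (up to the 6-significant-digit text
#' precision).  A sample sheet restores the condition labels.
#'
#' @param path FPKM TSV.
#' @param samples sample sheet data.frame or TSV path.
#' @param assay which assay's samples to select.
#' @return object of class `expression_table`.
#' @export
read_fpkm_tsv <- function(path, samples, assay = c("RNA", "RPF")) {
  assay <- match.arg(assay)
  df <- read_tsv(path, required = c("gene_id", "effective_length_nt"))
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  sheet <- samples[samples$assay == assay, , drop = FALSE]
  missing <- setdiff(sheet$sample_id, names(df))
  if (length(missing))
    stop("FPKM file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, sheet$sample_id, drop = FALSE])
  rownames(m) <- df$gene_id
  structure(list(fpkm = m,
                 effective_length_nt = setNames(df$effective_length_nt,
                                                df$gene_id),
                 library_size = NULL, assay = assay, samples = sheet),
            class = "expression_table")
}
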