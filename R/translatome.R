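# Translational efficiency: per-replicate TE, condition fold change, the
# per-gene significance test, the TE-sensitivity classification and the
# nine-quadrant transcriptome/translatome partition.

#' Analysis thresholds
#'
#' Cutoffs applied downstream of quantification.  Defaults: significance
#' level 0.05, absolute log2 fold-change cut 1 (two-fold), minimum mean
#' RNA FPKM 1 for a gene to be analysed, and pseudocount 0.5 added to both
#' FPKM values before forming the TE ratio.
#'
#' @param alpha significance level in (0, 1).
#' @param log2fc_cut non-negative log2 fold-change threshold.
#' @param min_fpkm non-negative detection floor on mean RNA FPKM.
#' @param pseudocount positive stabiliser added to FPKM before ratios.
#' @return validated list of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(alpha = 0.05, log2fc_cut = 1,
                                min_fpkm = 1, pseudocount = 0.5) {
  stopifnot_scalar(alpha, "alpha", lo = 1e-12, hi = 1 - 1e-12)
  stopifnot_scalar(log2fc_cut, "log2fc_cut", lo = 0)
  stopifnot_scalar(min_fpkm, "min_fpkm", lo = 0)
  stopifnot_scalar(pseudocount, "pseudocount", lo = 1e-12)
  structure(list(alpha = alpha, log2fc_cut = log2fc_cut,
                 min_fpkm = min_fpkm, pseudocount = pseudocount),
            class = "analysis_thresholds")
}

# pair Ribo-seq and RNA-seq samples by (condition, replicate)
pair_samples <- function(ribo_samples, rna_samples) {
  key <- function(s) paste(s$condition, s$replicate, sep = "_")
  rk <- key(ribo_samples); nk <- key(rna_samples)
  miss <- setdiff(rk, nk)
  if (length(miss))
    stop("no RNA sample paired with Ribo-seq (condition, replicate): ",
         paste(head(miss, 10), collapse = ", "), call. = FALSE)
  data.frame(pair_id = rk,
             ribo = ribo_samples$sample_id,
             rna = rna_samples$sample_id[match(rk, nk)],
             condition = ribo_samples$condition,
             replicate = ribo_samples$replicate,
             stringsAsFactors = FALSE)
}

#' Per-replicate translational efficiency
#'
#' TE = (FPKM_ribo + pseudocount) / (FPKM_rna + pseudocount) for each gene
#' in each (condition, replicate) pair.  Genes whose mean RNA FPKM falls
#' below `min_fpkm` in either condition are flagged `excluded` (kept in the
#' table but not classified downstream).
#'
#' @param fpkm_ribo,fpkm_rna [compute_fpkm()] outputs for the RPF and RNA
#'   assays over the same gene universe.
#' @param thresholds an [analysis_thresholds()].
#' @return list with `te` (genes x pairs matrix), `pairs` (the sample
#'   pairing sheet), `excluded` (named logical) and `thresholds`.
#' @export
compute_te <- function(fpkm_ribo, fpkm_rna,
                       thresholds = analysis_thresholds()) {
  g1 <- rownames(fpkm_ribo$fpkm); g2 <- rownames(fpkm_rna$fpkm)
  if (!setequal(g1, g2)) {
    diff <- c(setdiff(g1, g2), setdiff(g2, g1))
    stop("gene universes differ between assays; e.g.: ",
         paste(head(diff, 10), collapse = ", "), call. = FALSE)
  }
  rna <- fpkm_rna$fpkm[g1, , drop = FALSE]
  pairs <- pair_samples(fpkm_ribo$samples, fpkm_rna$samples)
  pc <- thresholds$pseudocount
  te <- (fpkm_ribo$fpkm[, pairs$ribo, drop = FALSE] + pc) /
    (rna[, pairs$rna, drop = FALSE] + pc)
  colnames(te) <- pairs$pair_id

  ctrl <- pairs$condition == "control"
  mean_rna_ctrl <- rowMeans(rna[, pairs$rna[ctrl], drop = FALSE])
  mean_rna_trt <- rowMeans(rna[, pairs$rna[!ctrl], drop = FALSE])
  excluded <- mean_rna_ctrl < thresholds$min_fpkm |
    mean_rna_trt < thresholds$min_fpkm
  names(excluded) <- g1
  list(te = te, pairs = pairs, excluded = excluded, thresholds = thresholds)
}

#' TE fold change between conditions
#'
#' Delta-TE = TE(treatment) / TE(control), with condition TE summarised as
#' the geometric mean over replicates (arithmetic mean on the log2 scale —
#' the natural summary for a ratio statistic).
#'
#' @param te_treatment,te_control positive per-replicate TE values (or
#'   already-summarised scalars).
#' @return list with `te_control`, `te_treatment` (geometric means),
#'   `delta_te` and `log2_delta_te`.
#' @export
compute_delta_te <- function(te_treatment, te_control) {
  if (any(te_treatment <= 0) || any(te_control <= 0))
    stop("TE values must be positive", call. = FALSE)
  tt <- 2^mean(log2(te_treatment))
  tc <- 2^mean(log2(te_control))
  list(te_control = tc, te_treatment = tt,
       delta_te = tt / tc, log2_delta_te = log2(tt) - log2(tc))
}

# row-wise Welch t-test on two matrices of replicate values; variances are
# floored so zero within-group variance yields a finite, extreme statistic
welch_rows <- function(X, Y, var_floor = 1e-8) {
  n1 <- ncol(X); n2 <- ncol(Y)
  if (n1 < 2L || n2 < 2L) {
    warning("fewer than 2 replicates per condition; p set to 1")
    return(rep(1, nrow(X)))
  }
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- pmax(rowSums((X - m1)^2) / (n1 - 1), var_floor)
  v2 <- pmax(rowSums((Y - m2)^2) / (n2 - 1), var_floor)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(tstat), df)
}

#' Test a per-gene TE change between conditions
#'
#' Two-sided test on per-replicate log2 TE.  The default is a Welch t-test
#' with an epsilon floor on the within-group variances (so degenerate
#' zero-variance replicates give an extreme but finite statistic).  The
#' exact permutation mode enumerates all relabelings of the pooled
#' replicates (available for up to 10 total replicates) and reports the
#' proportion of relabelings whose absolute mean difference reaches the
#' observed one.
#'
#' @param log2te_control,log2te_treatment numeric replicate vectors.
#' @param mode `"welch"` or `"permutation"`.
#' @param var_floor variance floor for the Welch path.
#' @return two-sided p-value.  With fewer than 2 replicates in either
#'   condition, returns 1 with a warning.
#' @export
test_te_change <- function(log2te_control, log2te_treatment,
                           mode = c("welch", "permutation"),
                           var_floor = 1e-8) {
  mode <- match.arg(mode)
  n1 <- length(log2te_control); n2 <- length(log2te_treatment)
  if (n1 < 2L || n2 < 2L) {
    warning("fewer than 2 replicates per condition; p set to 1")
    return(1)
  }
  if (mode == "welch")
    return(welch_rows(matrix(log2te_control, 1), matrix(log2te_treatment, 1),
                      var_floor))
  if (n1 + n2 > 10L)
    stop("exact permutation mode supports at most 10 total replicates",
         call. = FALSE)
  pooled <- c(log2te_control, log2te_treatment)
  obs <- abs(mean(log2te_treatment) - mean(log2te_control))
  labelings <- combn(n1 + n2, n1)
  stats <- apply(labelings, 2, function(idx)
    abs(mean(pooled[-idx]) - mean(pooled[idx])))
  mean(stats >= obs - 1e-12)
}

#' Classify genes by TE change
#'
#' A gene is TE-up when log2 delta-TE >= `log2fc_cut` and p <= `alpha`;
#' TE-down when log2 delta-TE <= -`log2fc_cut` and p <= `alpha`; otherwise
#' TE-insensitive.
#'
#' @param log2_delta_te,p_value numeric vectors (recycled to equal length).
#' @param thresholds an [analysis_thresholds()].
#' @return character vector over `{"up", "down", "insensitive"}` (NA where
#'   either input is NA).
#' @export
classify_te <- function(log2_delta_te, p_value,
                        thresholds = analysis_thresholds()) {
  cut <- thresholds$log2fc_cut; a <- thresholds$alpha
  out <- ifelse(log2_delta_te >= cut & p_value <= a, "up",
                ifelse(log2_delta_te <= -cut & p_value <= a, "down",
                       "insensitive"))
  out[is.na(log2_delta_te) | is.na(p_value)] <- NA_character_
  out
}

axis_status <- function(lfc, p, thresholds) {
  cut <- thresholds$log2fc_cut; a <- thresholds$alpha
  sig <- if (is.null(p)) rep(TRUE, length(lfc)) else p <= a
  ifelse(lfc >= cut & sig, "up", ifelse(lfc <= -cut & sig, "down", "flat"))
}

#' Nine-quadrant transcriptome/translatome partition
#'
#' Trichotomises the RNA (transcriptome) and RPF (translatome) log2 fold
#' changes at +/-`log2fc_cut`, gated by per-axis significance when p-values
#' are supplied, yielding one of nine labels
#' `"rna-{down,flat,up}_ribo-{down,flat,up}"`.  Translatome-only genes
#' change on the ribo axis while flat on the RNA axis.
#'
#' @param rna_log2fc,ribo_log2fc per-gene condition log2 fold changes of
#'   RNA FPKM and RPF FPKM.
#' @param rna_p,ribo_p optional per-axis p-values for the significance
#'   gate; omit (`NULL`) to trichotomise on fold change alone.
#' @param thresholds an [analysis_thresholds()].
#' @return character vector of quadrant labels.
#' @seealso [translatome_only()]
#' @export
nine_quadrant <- function(rna_log2fc, ribo_log2fc, rna_p = NULL,
                          ribo_p = NULL,
                          thresholds = analysis_thresholds()) {
  s_rna <- axis_status(rna_log2fc, rna_p, thresholds)
  s_ribo <- axis_status(ribo_log2fc, ribo_p, thresholds)
  out <- paste0("rna-", s_rna, "_ribo-", s_ribo)
  out[is.na(s_rna) | is.na(s_ribo)] <- NA_character_
  out
}

#' Identify translatome-only genes from quadrant labels
#'
#' @param quadrant labels from [nine_quadrant()].
#' @return logical: changed on the ribo axis, flat on the RNA axis.
#' @export
translatome_only <- function(quadrant) {
  grepl("^rna-flat_ribo-(up|down)$", quadrant)
}

#' Full translatome analysis table
#'
#' Runs the complete TE workflow: per-replicate TE, condition geometric
#' means, delta-TE, a per-gene two-sided test on replicate log2 TE,
#' Benjamini-Hochberg FDR, TE-sensitivity classification, per-axis RNA and
#' RPF log2 fold changes with their own tests, and the nine-quadrant
#' label.  The classification gate uses raw p-values by default (matching
#' the usual volcano presentation); set `gate = "fdr"` to gate on the
#' adjusted values instead.
#'
#' @param fpkm_ribo,fpkm_rna [compute_fpkm()] outputs for RPF and RNA.
#' @param thresholds an [analysis_thresholds()].
#' @param test per-gene test: `"welch"` (default) or `"permutation"`.
#' @param gate `"raw"` or `"fdr"`.
#' @return data.frame with one row per gene: `gene_id`, `te_ctrl`,
#'   `te_treat`, `delta_te`, `log2_delta_te`, `p`, `fdr`, `te_class`,
#'   `rna_log2fc`, `ribo_log2fc`, `quadrant`, `excluded`.
#' @export
te_analysis <- function(fpkm_ribo, fpkm_rna,
                        thresholds = analysis_thresholds(),
                        test = c("welch", "permutation"),
                        gate = c("raw", "fdr")) {
  test <- match.arg(test); gate <- match.arg(gate)
  te <- compute_te(fpkm_ribo, fpkm_rna, thresholds)
  pairs <- te$pairs
  ctrl <- pairs$condition == "control"
  l2te <- log2(te$te)
  Xc <- l2te[, ctrl, drop = FALSE]; Xt <- l2te[, !ctrl, drop = FALSE]

  te_ctrl <- 2^rowMeans(Xc); te_treat <- 2^rowMeans(Xt)
  log2_delta <- rowMeans(Xt) - rowMeans(Xc)

  p <- if (test == "welch") welch_rows(Xc, Xt)
  else vapply(seq_len(nrow(l2te)), function(i)
    test_te_change(Xc[i, ], Xt[i, ], mode = "permutation"), numeric(1))

  excluded <- te$excluded
  fdr <- rep(NA_real_, length(p))
  fdr[!excluded] <- p.adjust(p[!excluded], method = "BH")

  pc <- thresholds$pseudocount
  genes <- rownames(te$te)
  l2rna <- log2(fpkm_rna$fpkm[genes, pairs$rna, drop = FALSE] + pc)
  l2ribo <- log2(fpkm_ribo$fpkm[genes, pairs$ribo, drop = FALSE] + pc)
  rna_lfc <- rowMeans(l2rna[, !ctrl, drop = FALSE]) -
    rowMeans(l2rna[, ctrl, drop = FALSE])
  ribo_lfc <- rowMeans(l2ribo[, !ctrl, drop = FALSE]) -
    rowMeans(l2ribo[, ctrl, drop = FALSE])
  rna_p <- welch_rows(l2rna[, ctrl, drop = FALSE],
                      l2rna[, !ctrl, drop = FALSE])
  ribo_p <- welch_rows(l2ribo[, ctrl, drop = FALSE],
                       l2ribo[, !ctrl, drop = FALSE])

  gate_p <- if (gate == "raw") p else fdr
  te_class <- classify_te(log2_delta, gate_p, thresholds)
  quadrant <- nine_quadrant(rna_lfc, ribo_lfc, rna_p, ribo_p, thresholds)
  te_class[excluded] <- NA_character_
  quadrant[excluded] <- NA_character_

  data.frame(gene_id = genes, te_ctrl = te_ctrl, te_treat = te_treat,
             delta_te = te_treat / te_ctrl, log2_delta_te = log2_delta,
             p = p, fdr = fdr, te_class = te_class,
             rna_log2fc = rna_lfc, ribo_log2fc = ribo_lfc,
             quadrant = quadrant, excluded = excluded,
             row.names = NULL, stringsAsFactors = FALSE)
}
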