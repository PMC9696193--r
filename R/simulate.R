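# Synthetic translatome generator: transcript models with planted 5'UTR
# feature shifts, ground-truth TE classes, and paired RNA/RPF negative
# binomial count matrices.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic translatome generator.  The
#' defaults describe a desk-scale experiment: 2000 genes, two conditions
#' (control vs treatment) with 3 replicates each at 2 million fragments per
#' library, 10% of genes translationally up-regulated (planted TE fold
#' change 4) and 10% down-regulated (fold change 0.25).  TE-sensitive genes
#' carry the 5'UTR signature reported for translationally regulated
#' transcripts: GC content elevated by `gc_shift_points` percentage points
#' and 5'UTR length scaled by `len5_shift` relative to insensitive genes.
#'
#' @param n_genes number of genes to simulate.
#' @param n_replicates replicates per condition.
#' @param mean_depth expected total fragment count per library.
#' @param dispersion negative-binomial dispersion phi (>= 0; 0 gives
#'   Poisson counts).
#' @param frac_te_up,frac_te_down fractions of genes in the TE-up and
#'   TE-down classes (their sum must be <= 1).
#' @param effect_te_up,effect_te_down planted TE fold changes
#'   (treatment/control) for the two sensitive classes; must bracket 1.
#' @param gc_shift_points percentage-point GC elevation planted in
#'   TE-sensitive 5'UTRs.
#' @param len5_shift multiplicative 5'UTR length elevation in TE-sensitive
#'   genes.
#' @param base_gc5 baseline 5'UTR GC percent for insensitive genes.
#' @param mean_len5,sdlog_len5 log-normal location (nt, on the natural
#'   scale) and log-sd of insensitive 5'UTR lengths.
#' @param mean_len3,sdlog_len3 same for 3'UTR lengths.
#' @param mean_cds_codons,sdlog_cds same for CDS length in codons
#'   (including start and stop).
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   per-gene base abundance (arbitrary units; only relative values matter).
#' @param rpf_len_min,rpf_len_max support of simulated ribosome-protected
#'   fragment lengths (nt).
#' @param seed integer seed making every generator deterministic.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_replicates = 3, mean_depth = 2e6,
                       dispersion = 0.05,
                       frac_te_up = 0.1, frac_te_down = 0.1,
                       effect_te_up = 4, effect_te_down = 0.25,
                       gc_shift_points = 10, len5_shift = 1.5,
                       base_gc5 = 50,
                       mean_len5 = 150, sdlog_len5 = 0.45,
                       mean_len3 = 300, sdlog_len3 = 0.55,
                       mean_cds_codons = 400, sdlog_cds = 0.4,
                       abundance_meanlog = 1, abundance_sdlog = 1,
                       rpf_len_min = 26, rpf_len_max = 32,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_replicates = n_replicates,
              mean_depth = mean_depth, dispersion = dispersion,
              frac_te_up = frac_te_up, frac_te_down = frac_te_down,
              effect_te_up = effect_te_up, effect_te_down = effect_te_down,
              gc_shift_points = gc_shift_points, len5_shift = len5_shift,
              base_gc5 = base_gc5,
              mean_len5 = mean_len5, sdlog_len5 = sdlog_len5,
              mean_len3 = mean_len3, sdlog_len3 = sdlog_len3,
              mean_cds_codons = mean_cds_codons, sdlog_cds = sdlog_cds,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              rpf_len_min = rpf_len_min, rpf_len_max = rpf_len_max,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot_scalar(cfg$n_genes, "n_genes", lo = 1)
  stopifnot_scalar(cfg$n_replicates, "n_replicates", lo = 1)
  stopifnot_scalar(cfg$mean_depth, "mean_depth", lo = 0)
  stopifnot_scalar(cfg$dispersion, "dispersion", lo = 0)
  stopifnot_scalar(cfg$frac_te_up, "frac_te_up", lo = 0, hi = 1)
  stopifnot_scalar(cfg$frac_te_down, "frac_te_down", lo = 0, hi = 1)
  if (cfg$frac_te_up + cfg$frac_te_down > 1)
    stop("frac_te_up + frac_te_down must be <= 1", call. = FALSE)
  if (!(cfg$effect_te_down < 1 && 1 < cfg$effect_te_up))
    stop("need effect_te_down < 1 < effect_te_up", call. = FALSE)
  if (cfg$rpf_len_min > cfg$rpf_len_max)
    stop("rpf_len_min must be <= rpf_len_max", call. = FALSE)
  gc_target <- cfg$base_gc5 + cfg$gc_shift_points
  if (gc_target < 0 || gc_target > 100 || cfg$base_gc5 < 0 || cfg$base_gc5 > 100)
    stop("gc_shift_points pushes target GC% (", gc_target,
         ") outside [0, 100]", call. = FALSE)
  if (cfg$len5_shift <= 0) stop("len5_shift must be > 0", call. = FALSE)
  invisible(cfg)
}

# the 61 sense codons (RNA alphabet)
sense_codons <- function() {
  b <- c("A", "C", "G", "U")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("UAA", "UAG", "UGA"))
}

random_utr <- function(len, gc_percent) {
  p_gc <- gc_percent / 100
  vapply(len, function(l) {
    if (l == 0L) return("")
    paste(sample(c("G", "C", "A", "U"), l, replace = TRUE,
                 prob = c(p_gc / 2, p_gc / 2, (1 - p_gc) / 2, (1 - p_gc) / 2)),
          collapse = "")
  }, character(1))
}

random_cds <- function(n_codons) {
  codons <- sense_codons()
  stops <- c("UAA", "UAG", "UGA")
  vapply(n_codons, function(k) {
    internal <- if (k > 2L)
      sample(codons, k - 2L, replace = TRUE) else character(0)
    paste(c("AUG", internal, sample(stops, 1L)), collapse = "")
  }, character(1))
}

#' Generate synthetic transcript models with planted 5'UTR signatures
#'
#' Draws `n_genes` transcript models (5'UTR, CDS, 3'UTR over the RNA
#' alphabet) and assigns each gene a ground-truth TE class.  TE-sensitive
#' genes (up and down) receive 5'UTRs whose GC content is shifted by
#' `gc_shift_points` percentage points and whose length is scaled by
#' `len5_shift`, mirroring the structured-5'UTR signature of
#' translationally regulated transcripts.  Every CDS starts with AUG, ends
#' with a stop codon and has length divisible by 3.
#'
#' @param config a [sim_config()].
#' @return list with `models` (data.frame: gene_id, strand, utr5, cds,
#'   utr3) and `truth` (data.frame: gene_id, true_class, true_delta_te,
#'   true_gc5, true_len5).
#' @export
simulate_transcriptome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_genes)
  gene_id <- sprintf("g%04d", seq_len(n))

  n_up <- round(config$frac_te_up * n)
  n_down <- round(config$frac_te_down * n)
  cls <- rep("insensitive", n)
  cls[sample.int(n, n_up + n_down)] <- rep(c("up", "down"), c(n_up, n_down))

  sensitive <- cls != "insensitive"
  gc5 <- ifelse(sensitive, config$base_gc5 + config$gc_shift_points,
                config$base_gc5)
  len5 <- round(rlnorm(n, log(config$mean_len5), config$sdlog_len5) *
                  ifelse(sensitive, config$len5_shift, 1))
  len5 <- pmax(len5, 20L)
  len3 <- pmax(round(rlnorm(n, log(config$mean_len3), config$sdlog_len3)), 20L)
  n_codons <- pmax(round(rlnorm(n, log(config$mean_cds_codons),
                                config$sdlog_cds)), 10L)

  utr5 <- character(n)
  for (i in seq_len(n)) utr5[i] <- random_utr(len5[i], gc5[i])
  cds <- random_cds(n_codons)
  utr3 <- random_utr(len3, 40)

  delta <- ifelse(cls == "up", config$effect_te_up,
                  ifelse(cls == "down", config$effect_te_down, 1))

  list(models = data.frame(gene_id = gene_id, strand = "+", utr5 = utr5,
                           cds = cds, utr3 = utr3,
                           stringsAsFactors = FALSE),
       truth = data.frame(gene_id = gene_id, true_class = cls,
                          true_delta_te = delta, true_gc5 = gc5,
                          true_len5 = nchar(utr5),
                          stringsAsFactors = FALSE))
}

#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @param assay `"RNA"` or `"RPF"`.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`control`/`treatment`) and `replicate`, one row per column of
#'   `counts`.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, assay = c("RNA", "RPF"), samples) {
  assay <- match.arg(assay)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene rownames", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  required <- c("sample_id", "condition", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!identical(colnames(counts), as.character(samples$sample_id)))
    stop("counts columns must match samples$sample_id in order",
         call. = FALSE)
  if (!all(samples$condition %in% c("control", "treatment")))
    stop("condition must be 'control' or 'treatment'", call. = FALSE)
  if (length(unique(samples$condition)) < 2L)
    stop("need at least one sample per condition", call. = FALSE)
  structure(list(counts = counts, assay = assay, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s assay: %d genes x %d samples (%s)\n",
              x$assay, nrow(x$counts), ncol(x$counts),
              paste(table(x$samples$condition), collapse = "+")))
  invisible(x)
}

#' Simulate paired RNA and RPF count matrices
#'
#' Per-gene base abundances are drawn log-normal; counts are negative
#' binomial with shared dispersion (Poisson when `dispersion = 0`).  RNA
#' means are identical across conditions; treatment RPF means are the
#' control means multiplied by each gene's planted TE fold change, so the
#' expected ratio of RPF/RNA count ratios equals `true_delta_te`.
#'
#' @param models,truth output of [simulate_transcriptome()] (aligned by
#'   gene_id).
#' @param config a [sim_config()].
#' @return list with `rna` and `rpf` [count_matrix()] objects and the
#'   combined `samples` sheet.
#' @export
simulate_counts <- function(models, truth, config) {
  validate_sim_config(config)
  if (nrow(models) == 0L) stop("empty model list", call. = FALSE)
  if (!identical(models$gene_id, truth$gene_id))
    stop("models and truth must be aligned by gene_id", call. = FALSE)
  set.seed(config$seed + 1L)
  n <- nrow(models)
  reps <- as.integer(config$n_replicates)

  abundance <- rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  rel <- abundance / sum(abundance)
  mu_rna <- config$mean_depth * rel
  mu_rpf_ctrl <- config$mean_depth * rel
  mu_rpf_trt <- mu_rpf_ctrl * truth$true_delta_te

  draw <- function(mu) {
    if (config$dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  make_mat <- function(mu_ctrl, mu_trt) {
    m <- cbind(matrix(unlist(lapply(seq_len(reps), function(r) draw(mu_ctrl))),
                      ncol = reps),
               matrix(unlist(lapply(seq_len(reps), function(r) draw(mu_trt))),
                      ncol = reps))
    rownames(m) <- models$gene_id
    m
  }
  sheet <- function(assay) {
    data.frame(sample_id = paste(assay,
                                 rep(c("control", "treatment"), each = reps),
                                 rep(seq_len(reps), 2), sep = "_"),
               condition = rep(c("control", "treatment"), each = reps),
               assay = assay, replicate = rep(seq_len(reps), 2),
               stringsAsFactors = FALSE)
  }
  rna_samples <- sheet("RNA")
  rpf_samples <- sheet("RPF")
  rna_counts <- make_mat(mu_rna, mu_rna)
  rpf_counts <- make_mat(mu_rpf_ctrl, mu_rpf_trt)
  colnames(rna_counts) <- rna_samples$sample_id
  colnames(rpf_counts) <- rpf_samples$sample_id

  list(rna = count_matrix(rna_counts, "RNA", rna_samples),
       rpf = count_matrix(rpf_counts, "RPF", rpf_samples),
       samples = rbind(rna_samples, rpf_samples))
}

#' Simulate ribosome-protected fragment lengths
#'
#' Lengths are drawn from a shifted binomial over
#' `[rpf_len_min, rpf_len_max]` whose mode sits at 29 nt (clamped into the
#' support), reproducing the unimodal 26-32 nt RPF size distribution with
#' most fragments in the 28-30 nt analysis window.
#'
#' @param n number of fragments.
#' @param config a [sim_config()].
#' @param seed optional seed override (defaults to `config$seed + 2`).
#' @return integer vector of `n` lengths.
#' @export
simulate_rpf_lengths <- function(n, config, seed = config$seed + 2L) {
  validate_sim_config(config)
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n == 0L) return(integer(0))
  set.seed(seed)
  span <- config$rpf_len_max - config$rpf_len_min
  if (span == 0L) return(rep(config$rpf_len_min, n))
  mode_target <- min(max(29L, config$rpf_len_min), config$rpf_len_max)
  p <- (mode_target - config$rpf_len_min) / span
  config$rpf_len_min + rbinom(n, span, p)
}

#' Simulate a toy gene-set collection with one planted enriched set
#'
#' Builds `n_sets` gene sets over the simulated gene universe.  The first
#' set (`planted_set`) draws `planted_frac` of its members from the chosen
#' ground-truth class, making it detectably over-represented among that
#' class's genes; the remaining sets are uniform draws.
#'
#' @param truth ground-truth table from [simulate_transcriptome()].
#' @param n_sets,set_size collection dimensions.
#' @param planted_class the true class the planted set is enriched for.
#' @param planted_frac fraction of the planted set drawn from that class.
#' @param seed integer seed.
#' @return named list of gene-id vectors; the planted set is named
#'   `"planted_<class>_set"`.
#' @export
simulate_gene_sets <- function(truth, n_sets = 20, set_size = 50,
                               planted_class = "down", planted_frac = 0.8,
                               seed = 1) {
  set.seed(seed)
  universe <- truth$gene_id
  in_class <- truth$gene_id[truth$true_class == planted_class]
  k_in <- min(round(planted_frac * set_size), length(in_class))
  planted <- c(sample(in_class, k_in),
               sample(setdiff(universe, in_class), set_size - k_in))
  others <- lapply(seq_len(n_sets - 1L),
                   function(i) sample(universe, min(set_size, length(universe))))
  sets <- c(list(planted), others)
  names(sets) <- c(paste0("planted_", planted_class, "_set"),
                   sprintf("random_set_%02d", seq_len(n_sets - 1L)))
  sets
}

#' Run the full simulator
#'
#' Convenience wrapper chaining [simulate_transcriptome()],
#' [simulate_counts()] and [simulate_rpf_lengths()].
#'
#' @param config a [sim_config()].
#' @param n_rpf_lengths how many fragment lengths to draw.
#' @return list with `models`, `truth`, `rna`, `rpf`, `samples`,
#'   `rpf_lengths` and the `config` used.
#' @export
simulate_translatome <- function(config = sim_config(),
                                 n_rpf_lengths = 1e5) {
  tx <- simulate_transcriptome(config)
  cnt <- simulate_counts(tx$models, tx$truth, config)
  list(models = tx$models, truth = tx$truth,
       rna = cnt$rna, rpf = cnt$rpf, samples = cnt$samples,
       rpf_lengths = simulate_rpf_lengths(n_rpf_lengths, config),
       config = config)
}
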