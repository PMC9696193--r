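# Pipeline configuration and the end-to-end runner chaining
# simulate -> quantify (RNA, RPF) -> TE -> features -> enrichment.

#' Default pipeline configuration
#'
#' A nested list holding every tunable parameter of the pipeline, written
#' alongside each run so all analysis choices are auditable.  Stages:
#' `simulate` ([sim_config()] fields; set to `NULL` and supply `counts`
#' paths to analyse user data), `thresholds` ([analysis_thresholds()]
#' fields), `rpf_window` (fragment-length analysis window), `fold`
#' (pair-energy model for 5'UTR folding) and `enrichment` (set-size gates
#' and which TE class forms the query).
#'
#' @param outdir output directory for the run.
#' @param seed integer seed driving every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "ribote_run", seed = 1) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = unclass(sim_config(seed = as.integer(seed))),
    counts = NULL,  # list(rna=, rpf=, samples=, fasta=) to skip simulation
    gmt = NULL,     # path to a GMT; NULL simulates a toy collection
    rpf_window = c(28, 30),
    thresholds = unclass(analysis_thresholds()),
    fold = list(energies = c(GC = -3, AU = -2, GU = -1), min_loop = 3),
    enrichment = list(min_set = 5, max_set = 500, class = "down",
                      n_sets = 20, set_size = 50)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' The config round-trips read -> write -> read identically.
#'
#' @param path YAML file.
#' @return for `read_pipeline_config`, a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config()
  for (nm in names(cfg)) base[nm] <- list(modify_defaults(base[[nm]],
                                                          cfg[[nm]]))
  if (!is.null(base$fold$energies))
    base$fold$energies <- unlist(base$fold$energies)
  base$seed <- as.integer(base$seed)
  base
}

modify_defaults <- function(default, value) {
  if (is.list(default) && is.list(value)) {
    for (nm in names(value)) default[nm] <- list(value[[nm]])
    default
  } else value
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes, in order: simulation (unless user count matrices are
#' supplied), RPF length filtering summary, FPKM quantification of both
#' assays, TE/delta-TE analysis with classification and nine-quadrant
#' partition, sequence-feature extraction with class comparisons, and
#' gene-set enrichment of the chosen TE class.  Every stage's output is
#' written as TSV/FASTA under `config$outdir`, followed by an atomically
#' written JSON run manifest.  A failing stage aborts with its name;
#' outputs of earlier stages are left intact.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest, invisibly.
#' @export
run_all <- function(config = pipeline_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  inputs <- character(0)
  counts_written <- list()

  if (is.null(config$counts)) {
    sim <- run_stage("simulate", {
      scfg <- do.call(sim_config, config$simulate)
      simulate_translatome(scfg)
    })
    models <- sim$models; truth <- sim$truth
    rna <- sim$rna; rpf <- sim$rpf
    write_fasta(models_to_fasta(models), out("transcripts.fasta"))
    write_annotation(models, out("annotation.gtf"))
    write_counts_tsv(rna, out("counts_rna.tsv"))
    write_counts_tsv(rpf, out("counts_rpf.tsv"))
    write_tsv(sim$samples, out("samples.tsv"))
    write_tsv(truth, out("ground_truth.tsv"))
    kept <- filter_rpf_lengths(sim$rpf_lengths, config$rpf_window)
    write_tsv(data.frame(metric = c("n_fragments", "n_in_window"),
                         value = c(length(sim$rpf_lengths), length(kept))),
              out("rpf_length_filter.tsv"))
  } else {
    sim <- NULL; truth <- NULL
    for (p in unlist(config$counts))
      if (!file.exists(p)) stop("stage 'input' failed: file not found: ", p,
                                call. = FALSE)
    inputs <- unlist(config$counts)
    samples <- read_sample_sheet(config$counts$samples)
    rna <- run_stage("input", read_counts_tsv(config$counts$rna, samples,
                                              "RNA"))
    rpf <- run_stage("input", read_counts_tsv(config$counts$rpf, samples,
                                              "RPF"))
    models <- run_stage("input",
                        fasta_to_models(read_fasta(config$counts$fasta)))
  }

  fpkm <- run_stage("quantify", {
    list(rna = compute_fpkm(rna, effective_lengths(models, "RNA")),
         rpf = compute_fpkm(rpf, effective_lengths(models, "RPF")))
  })
  write_fpkm_tsv(fpkm$rna, out("fpkm_rna.tsv"))
  write_fpkm_tsv(fpkm$rpf, out("fpkm_rpf.tsv"))

  thr <- do.call(analysis_thresholds, config$thresholds)
  te <- run_stage("te", te_analysis(fpkm$rpf, fpkm$rna, thr))
  write_tsv(te, out("te_table.tsv"))

  features <- run_stage("features",
                        feature_table(models, config$fold$energies,
                                      config$fold$min_loop))
  write_tsv(features, out("features.tsv"))
  comparisons <- run_stage("features",
                           compare_feature_distributions(features, te))
  write_tsv(comparisons, out("feature_comparisons.tsv"))

  enr <- run_stage("enrich", {
    sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)
    else {
      if (is.null(truth))
        stop("no GMT supplied and no simulated truth to build one from")
      simulate_gene_sets(truth, n_sets = config$enrichment$n_sets,
                         set_size = config$enrichment$set_size,
                         planted_class = config$enrichment$class,
                         seed = config$seed + 3L)
    }
    if (is.null(config$gmt)) write_gmt(sets, out("gene_sets.gmt"))
    cls <- config$enrichment$class
    query <- if (cls == "sensitive")
      te$gene_id[!is.na(te$te_class) & te$te_class != "insensitive"]
    else te$gene_id[!is.na(te$te_class) & te$te_class == cls]
    universe <- te$gene_id[!te$excluded]
    enrich(query, sets, universe, config$enrichment$min_set,
           config$enrichment$max_set)
  })
  write_tsv(enr, out("enrichment.tsv"))

  write_pipeline_config(config, out("config.yaml"))

  manifest <- list(
    tool = "riboTE",
    version = as.character(utils::packageVersion("riboTE")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(out("config.yaml"))),
    input_md5 = as.list(tools::md5sum(inputs)),
    rows = list(genes = nrow(te), analysed = sum(!te$excluded),
                te_up = sum(te$te_class == "up", na.rm = TRUE),
                te_down = sum(te$te_class == "down", na.rm = TRUE),
                translatome_only = sum(translatome_only(te$quadrant),
                                       na.rm = TRUE),
                feature_comparisons = nrow(comparisons),
                gene_sets = nrow(enr)),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  tmp <- tempfile(tmpdir = config$outdir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, out("manifest.json"))
  invisible(manifest)
}
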