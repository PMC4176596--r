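# End-to-end orchestration: synthetic inputs through the expression and
# miRNA pipelines, direction calls joined into the concordance test, all
# stage outputs and a machine-readable manifest written to a run directory.

default_pipeline_config <- function() {
  list(seed = 1L,
       array = list(),           # overrides for array_sim_config
       mirna = list(),           # overrides for mirna_sim_config
       fdr_threshold = 0.05,
       z_threshold = 4,
       min_reads = 4L,
       loess_span = 0.3,
       monotone_fdr = FALSE,
       utr_default_length = 2482L)
}

#' Validate a pipeline configuration
#'
#' @param config named list; unknown keys are a validation error. See
#'   \code{\link{run_pipeline}} for the recognized keys and defaults.
#' @return the completed configuration.
#' @export
validate_pipeline_config <- function(config = list()) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    fail("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  if (cfg$fdr_threshold <= 0 || cfg$z_threshold <= 0 || cfg$min_reads <= 0 ||
      cfg$utr_default_length <= 0)
    fail("thresholds must be positive")
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic two-color experiment and small-RNA libraries from
#' one seed, runs the gender differential-expression and miRNA deviation
#' pipelines, pairs every significant miRNA with every significant gene
#' probe as candidate targets and scores concordance, then writes all
#' stage outputs (TSV) and a JSON manifest with parameters, seeds and
#' per-stage record counts. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config named list of overrides accepted by
#'   \code{\link{validate_pipeline_config}}: \code{seed}, \code{array}
#'   (arguments of \code{\link{array_sim_config}}), \code{mirna}
#'   (arguments of \code{\link{mirna_sim_config}}),
#'   \code{fdr_threshold}, \code{z_threshold}, \code{min_reads},
#'   \code{loess_span}, \code{monotone_fdr}, \code{utr_default_length}.
#' @param out_dir run directory (created; existing files overwritten).
#' @return invisibly, a list with the stage objects and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_pipeline_config(config)
  if (missing(out_dir)) fail("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                     file = logf, append = TRUE)
  cat(sprintf("pipeline run, seed %d\n", cfg$seed), file = logf)

  acfg <- do.call(array_sim_config,
                  utils::modifyList(list(seed = cfg$seed), cfg$array))
  exper <- generate_microarray_experiment(acfg)
  log_line("arrays: %d probes x %d samples, %d planted DE probes",
           nrow(exper$R), nrow(exper$design), nrow(exper$truth))
  de <- gender_de_pipeline(exper, fdr_threshold = cfg$fdr_threshold,
                           span = cfg$loess_span,
                           monotone_fdr = cfg$monotone_fdr)
  log_line("expression DE: %d tested, %d significant", de$n_tested,
           nrow(de$significant))
  write_tsv(de$results, file.path(out_dir, "probe_results.tsv"))

  mcfg <- do.call(mirna_sim_config,
                  utils::modifyList(list(seed = cfg$seed + 1L), cfg$mirna))
  libs <- generate_mirna_libraries(mcfg)
  mde <- mirna_de_pipeline(libs, min_reads = cfg$min_reads,
                           z_threshold = cfg$z_threshold)
  log_line("miRNA DE: %d records, %d unique significant",
           nrow(mde$records), nrow(mde$unique_significant))
  write_tsv(mde$records, file.path(out_dir, "mirna_records.tsv"))
  write_tsv(mde$unique_significant,
            file.path(out_dir, "mirna_significant.tsv"))

  gene_calls <- direction_calls(de)
  mirna_calls <- direction_calls(mde)
  conc <- NULL
  if (nrow(gene_calls) && nrow(mirna_calls)) {
    pairs <- expand.grid(mirna_id = mirna_calls$entity_id,
                         gene_id = gene_calls$entity_id,
                         stringsAsFactors = FALSE)
    scored <- score_concordance(mirna_calls, gene_calls, pairs)
    conc <- concordance_report(scored)
    write_tsv(conc, file.path(out_dir, "concordance.tsv"))
    log_line("concordance: %d pairs over %d miRNAs", nrow(scored),
             nrow(conc))
  } else log_line("concordance skipped: no significant calls on one side")

  manifest <- list(
    package_version = as.character(utils::packageVersion("sexdimorph")),
    seed = cfg$seed, parameters = cfg[setdiff(names(cfg), "seed")],
    counts = list(
      probes_tested = de$n_tested,
      probes_significant = nrow(de$significant),
      planted_de_probes = nrow(exper$truth),
      mirna_records = nrow(mde$records),
      mirna_unique_significant = nrow(mde$unique_significant),
      planted_de_mirnas = length(unique(libs$truth$mirna_id)),
      concordance_pairs = if (is.null(conc)) 0L else sum(conc$n_targets)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(expression = de, mirna = mde, concordance = conc,
                 experiment = exper, libraries = libs, manifest = manifest))
}
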