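# end-to-end workflow: filter -> contrasts -> venn -> classify -> enrich,
# with a reproducibility manifest

#' Run the knockout transcriptome pipeline
#'
#' Executes the full workflow on a TPM study: expression filtering,
#' the three mutant-vs-WT contrasts, the Venn summary, isoform-dominance
#' classification, and (optionally) gene-set overrepresentation of the
#' NDKO up- and downregulated DEG lists against each supplied GMT library,
#' using the post-filter expressed genes as the universe. All tables are
#' written as TSV under `outdir` together with a JSON manifest recording
#' parameters, seed, package version and input/output checksums.
#' Re-running with an identical configuration and inputs reproduces
#' byte-identical tables.
#'
#' @param config Either a YAML file path or a list with elements:
#'   \describe{
#'     \item{matrix, design}{paths to the TPM and design TSVs, or}
#'     \item{simulate}{a list of [sim_config()] arguments used to generate
#'       the study in place of file inputs (truth table also written);}
#'     \item{gmt}{optional named list/vector of GMT file paths;}
#'     \item{thresholds}{optional list: `expression_quantile` (0.25),
#'       `fc_threshold` (1.5), `p_threshold` (0.05), `fc_secondary` (1.3),
#'       `min_term_size` (3), `pseudocount` (1);}
#'     \item{seed}{integer, used only by the simulation block.}
#'   }
#' @param outdir Output directory (created if needed). Overrides
#'   `config$outdir`.
#' @return Invisibly, a list with the in-memory tables (`study`,
#'   `contrasts`, `venn`, `classes`, `enrichment`, `truth`) and `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_stage("config", "config must be a list or path")
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop_stage("config", "no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  th <- config$thresholds %||% list()
  quantile <- th$expression_quantile %||% 0.25
  fc_threshold <- th$fc_threshold %||% 1.5
  p_threshold <- th$p_threshold %||% 0.05
  fc_secondary <- th$fc_secondary %||% 1.3
  min_term_size <- th$min_term_size %||% 3
  pseudocount <- th$pseudocount %||% 1

  inputs <- character()
  truth <- NULL

  # --- load or simulate ---
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    if (!is.null(sim_args$class_fractions)) {
      sim_args$class_fractions <- unlist(sim_args$class_fractions)
    }
    sim <- tryCatch(simulate_expression(do.call(sim_config, sim_args)),
                    error = function(e) stop_stage("simulate",
                                                   conditionMessage(e)))
    study <- sim$study
    truth <- sim$truth
    write_tsv(truth, file.path(outdir, "truth.tsv"))
    write_expression(study, file.path(outdir, "tpm.tsv"),
                     file.path(outdir, "design.tsv"))
  } else if (!is.null(config$matrix) && !is.null(config$design)) {
    study <- tryCatch(read_expression(config$matrix, config$design),
                      error = function(e) stop_stage("read",
                                                     conditionMessage(e)))
    inputs <- c(inputs, matrix = config$matrix, design = config$design)
  } else {
    stop_stage("config", "need either matrix+design paths or a simulate block")
  }

  # --- filter ---
  filtered <- tryCatch(filter_expressed(study, quantile = quantile),
                       error = function(e) stop_stage("filter",
                                                      conditionMessage(e)))
  message(sprintf("[filter] kept %d of %d genes (top %.0f%% by mean TPM)",
                  nrow(filtered$tpm), nrow(study$tpm), 100 * quantile))

  # --- contrasts ---
  contrasts <- tryCatch(
    contrast_all(filtered, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, pseudocount = pseudocount),
    error = function(e) stop_stage("contrast", conditionMessage(e)))
  write_tsv(contrasts, file.path(outdir, "contrasts.tsv"),
            meta = sprintf("DEG criteria: fc > %g (or < 1/%g), p < %g",
                           fc_threshold, fc_threshold, p_threshold))

  # --- venn + classification ---
  venn <- tryCatch(venn_summary(contrasts),
                   error = function(e) stop_stage("venn",
                                                  conditionMessage(e)))
  write_tsv(venn, file.path(outdir, "venn_summary.tsv"))
  classes <- tryCatch(classify_isoforms(contrasts,
                                        fc_secondary = fc_secondary),
                      error = function(e) stop_stage("classify",
                                                     conditionMessage(e)))
  write_tsv(classes, file.path(outdir, "isoform_classes.tsv"),
            meta = sprintf("secondary fold-change bound: %g", fc_secondary))

  # --- enrichment ---
  enrichment <- list()
  gmt_paths <- config$gmt
  if (is.null(gmt_paths) || length(gmt_paths) == 0L) {
    message("[enrich] no GMT libraries supplied; enrichment stage skipped")
  } else {
    gmt_paths <- unlist(gmt_paths)
    if (is.null(names(gmt_paths)) || any(!nzchar(names(gmt_paths)))) {
      names(gmt_paths) <- tools::file_path_sans_ext(basename(gmt_paths))
    }
    universe <- rownames(filtered$tpm)
    nd <- contrasts[contrasts$genotype == "NDKO", , drop = FALSE]
    queries <- list(ndko_up = nd$gene[nd$deg_up],
                    ndko_down = nd$gene[nd$deg_down])
    for (lib_name in names(gmt_paths)) {
      lib <- tryCatch(read_gmt(gmt_paths[[lib_name]]),
                      error = function(e) stop_stage("enrich",
                                                     conditionMessage(e)))
      inputs <- c(inputs, stats::setNames(gmt_paths[[lib_name]], lib_name))
      for (qn in names(queries)) {
        tab <- tryCatch(enrich(queries[[qn]], lib, universe,
                               min_term_size = min_term_size),
                        error = function(e) stop_stage("enrich",
                                                       conditionMessage(e)))
        key <- paste(lib_name, qn, sep = "_")
        enrichment[[key]] <- tab
        write_tsv(tab, file.path(outdir, paste0("enrichment_", key, ".tsv")),
                  meta = sprintf("library=%s query=%s universe=%d genes",
                                 lib_name, qn, length(universe)))
      }
    }
  }

  # --- manifest ---
  out_files <- sort(setdiff(list.files(outdir, full.names = FALSE),
                            "manifest.json"))
  manifest <- list(
    tool = "kodeg",
    version = as.character(utils::packageVersion("kodeg")),
    seed = config$seed %||% NA,
    parameters = list(expression_quantile = quantile,
                      fc_threshold = fc_threshold,
                      p_threshold = p_threshold,
                      fc_secondary = fc_secondary,
                      min_term_size = min_term_size,
                      pseudocount = pseudocount),
    inputs = as.list(if (length(inputs) > 0L)
      vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
      else stats::setNames(list(), character())),
    outputs = as.list(vapply(file.path(outdir, out_files),
                             function(p) unname(tools::md5sum(p)),
                             character(1)) |>
                        stats::setNames(out_files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")

  invisible(list(study = filtered, contrasts = contrasts, venn = venn,
                 classes = classes, enrichment = enrichment, truth = truth,
                 manifest = manifest))
}
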