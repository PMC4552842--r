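#' Pipeline configuration
#'
#' Assembles and validates the configuration for \code{\link{runPipeline}}.
#' Round-trips losslessly through YAML via \code{\link{readPipelineConfig}}
#' and \code{\link{writePipelineConfig}}.
#'
#' @param inputDir directory of cohort files (see \code{\link{readCohort}});
#'   \code{NULL} (default) simulates a cohort instead.
#' @param sim named list of overrides for \code{\link{simulationParams}}
#'   (used only when \code{inputDir} is NULL).
#' @param zCutoff |z| cutoff for DEG selection (default 2).
#' @param zScale \code{"log2"} or \code{"linear"} standardization scale.
#' @param alpha significance level for grade association (default 0.05).
#' @param detectAlpha one-sided level for the detectability filter.
#' @param detectMinFraction detectability retention quorum.
#' @param maxMissingFraction bad-spot probe drop fraction.
#' @param diseases disease subset for grade association.
#' @param markerGenes gene panel to score (default
#'   \code{\link{markerPanel}}).
#' @param markersFromSelection score the genes discovered by
#'   dual-endpoint selection instead of \code{markerGenes} (default FALSE,
#'   mirroring a fixed pre-specified panel).
#' @param cuts grade cut points for the AUC table.
#' @param thresholdMethod \code{"youden"} or \code{"max-accuracy"}.
#' @param seed RNG seed for simulation.
#' @param outDir output directory; \code{NULL} for no file output.
#' @return A validated list of class \code{ckdms_config}.
#' @export
pipelineConfig <- function(inputDir = NULL, sim = list(), zCutoff = 2,
                           zScale = "log2", alpha = 0.05,
                           detectAlpha = 0.05, detectMinFraction = 0.5,
                           maxMissingFraction = 0.2,
                           diseases = glomerulopathyCategories(),
                           markerGenes = markerPanel(),
                           markersFromSelection = FALSE,
                           cuts = c(1L, 2L, 3L),
                           thresholdMethod = "youden", seed = 1L,
                           outDir = NULL) {
  config <- list(inputDir = inputDir, sim = sim, zCutoff = zCutoff,
                 zScale = zScale, alpha = alpha, detectAlpha = detectAlpha,
                 detectMinFraction = detectMinFraction,
                 maxMissingFraction = maxMissingFraction,
                 diseases = diseases, markerGenes = markerGenes,
                 markersFromSelection = markersFromSelection,
                 cuts = as.integer(cuts),
                 thresholdMethod = thresholdMethod,
                 seed = as.integer(seed), outDir = outDir)
  .validateConfig(config)
  class(config) <- "ckdms_config"
  config
}

.validateConfig <- function(config) {
  chk <- function(cond, field, what)
    if (!cond) stop(sprintf("config$%s: %s", field, what), call. = FALSE)
  chk(config$zCutoff > 0, "zCutoff", "must be > 0")
  chk(config$zScale %in% c("log2", "linear"), "zScale",
      "must be 'log2' or 'linear'")
  chk(config$alpha >= 0 && config$alpha <= 1, "alpha", "must be in [0, 1]")
  chk(config$detectAlpha > 0 && config$detectAlpha < 1, "detectAlpha",
      "must be in (0, 1)")
  chk(config$detectMinFraction >= 0 && config$detectMinFraction <= 1,
      "detectMinFraction", "must be in [0, 1]")
  chk(config$maxMissingFraction >= 0 && config$maxMissingFraction < 1,
      "maxMissingFraction", "must be in [0, 1)")
  chk(length(config$diseases) > 0, "diseases", "must be nonempty")
  chk(length(config$markerGenes) > 0, "markerGenes", "must be nonempty")
  chk(all(config$cuts >= .GRADE_MIN & config$cuts < .GRADE_MAX), "cuts",
      "must be grade cut points within [0, 5)")
  chk(config$thresholdMethod %in% c("youden", "max-accuracy"),
      "thresholdMethod", "must be 'youden' or 'max-accuracy'")
  invisible(TRUE)
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' @rdname pipelineConfig
#' @param config a \code{ckdms_config}.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.stageLog <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the end-to-end pipeline
#'
#' Orchestrates simulate/read, bad-spot handling, median normalization,
#' detectability filtering, fold-change computation, z-score DEG selection,
#' dual-endpoint grade association on the disease-restricted discovery
#' subset, molecular scoring, grade-dichotomization AUCs, threshold
#' derivation and validation-set prediction. Stage outputs are written
#' under \code{config$outDir} when set (\code{fold_change.tsv},
#' \code{deg.tsv}, \code{association.tsv}, \code{scores.tsv},
#' \code{roc.tsv}, \code{thresholds.json}, \code{predictions.tsv},
#' \code{report.json}); identical config and seed give an identical report
#' apart from its timestamp.
#'
#' @param config a \code{\link{pipelineConfig}} (or path to a YAML config).
#' @param verbose emit one structured log line per stage (default TRUE).
#' @return The run report, an invisible list of per-stage counts and
#'   results.
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  .validateConfig(config)

  cohort <- if (!is.null(config$inputDir)) {
    .stageLog(verbose, "input", "reading cohort from %s", config$inputDir)
    readCohort(config$inputDir)
  } else {
    params <- do.call(simulationParams, c(config$sim,
                                          list(seed = config$seed)))
    .stageLog(verbose, "simulate",
              "%d probes x %d samples (seed %d)", params@nProbes,
              params@nDiscovery + params@nValidation, params@seed)
    generateCohort(params)
  }

  clean <- dropBadSpots(cohort, config$maxMissingFraction)
  .stageLog(verbose, "bad-spots", "%d -> %d probes", nrow(cohort),
            nrow(clean))
  norm <- medianNormalize(clean)
  det <- filterDetectable(norm, alpha = config$detectAlpha,
                          minFraction = config$detectMinFraction)
  .stageLog(verbose, "detectability", "%d of %d probes detectable",
            sum(det$probeDetectable), nrow(norm))
  fc <- computeFoldChange(norm, detectable = det$probeDetectable)

  deg <- zscoreFoldChanges(fc, scale = config$zScale,
                           cutoff = config$zCutoff)
  lists <- selectDEG(deg)
  .stageLog(verbose, "deg", "%d up / %d down of %d probes",
            length(lists$up), length(lists$down), nrow(degTable(deg)))

  subsetIds <- subsetByDisease(fc, config$diseases)
  assoc <- dualEndpointSelection(fc, candidates = lists$up,
                                 samples = subsetIds,
                                 alpha = config$alpha)
  sig <- significantGenes(assoc)
  .stageLog(verbose, "associate",
            "%d candidates on %d samples: fibrosis %d, tubular %d, both %d genes",
            length(lists$up), length(subsetIds), length(sig$fibrosis),
            length(sig$tubular), length(sig$both))

  genes <- config$markerGenes
  if (config$markersFromSelection) {
    if (length(sig$both)) {
      genes <- sig$both
    } else {
      warning("dual-endpoint selection returned no genes; ",
              "falling back to the configured marker panel")
    }
  }
  discoveryIds <- colnames(fc)[colData(fc)$role == "discovery"]
  scoreAll <- molecularScore(fc, genes = genes)
  scoreDiscovery <- scoreValues(scoreAll)[discoveryIds]
  .stageLog(verbose, "score", "%d genes / %d probes on %d samples",
            length(genes), length(markerProbes(scoreAll)), ncol(fc))

  aucTab <- gradeDichotomizationAuc(scoreDiscovery, colData(fc),
                                    cuts = config$cuts)
  thresholds <- deriveThresholds(scoreDiscovery, colData(fc),
                                 method = config$thresholdMethod)
  .stageLog(verbose, "thresholds", "I = %.4g, II = %.4g",
            thresholdI(thresholds), thresholdII(thresholds))
  predictions <- validateCohort(fc, thresholds, genes = genes,
                                markerProbes = markerProbes(scoreAll))
  .stageLog(verbose, "validate", "%d validation samples",
            nrow(predictions))

  report <- list(
    package_version = as.character(utils::packageVersion("ckdms")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "outDir")],
    stages = list(
      input = list(n_probes = nrow(cohort), n_samples = ncol(cohort)),
      bad_spots = list(n_probes_retained = nrow(clean)),
      detectability = list(n_detectable = sum(det$probeDetectable)),
      deg = list(n_scored = nrow(degTable(deg)),
                 n_up = length(lists$up), n_down = length(lists$down)),
      association = list(n_candidates = length(lists$up),
                         n_samples = length(subsetIds),
                         n_genes_fibrosis = length(sig$fibrosis),
                         n_genes_tubular = length(sig$tubular),
                         n_genes_both = length(sig$both),
                         genes_both = sig$both),
      score = list(genes = genes,
                   n_marker_probes = length(markerProbes(scoreAll))),
      roc = aucTab,
      thresholds = list(threshold_I = thresholdI(thresholds),
                        threshold_II = thresholdII(thresholds),
                        method = thresholds@method),
      validation = list(
        n = nrow(predictions),
        concordant_I_fibrosis = sum(predictions$concordant_I_fibrosis),
        concordant_I_tubular = sum(predictions$concordant_I_tubular),
        concordant_II_fibrosis = sum(predictions$concordant_II_fibrosis),
        concordant_II_tubular = sum(predictions$concordant_II_tubular))),
    results = list(fold_change = fc, deg = deg, association = assoc,
                   score = scoreAll, thresholds = thresholds,
                   predictions = predictions))

  if (!is.null(config$outDir))
    .writePipelineOutputs(report, fc, deg, assoc, scoreAll, aucTab,
                          thresholds, predictions, config$outDir)
  invisible(report)
}

.writePipelineOutputs <- function(report, fc, deg, assoc, score, aucTab,
                                  thresholds, predictions, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  w <- function(dt, name)
    data.table::fwrite(dt, file.path(outDir, name), sep = "\t")
  fcTab <- data.table::data.table(
    probe_id = rownames(fc), gene = rowData(fc)$gene,
    cohort_mean_ratio = rowData(fc)$meanRatio,
    detectable = as.integer(rowData(fc)$detectable))
  fcTab <- cbind(fcTab,
                 data.table::as.data.table(assay(fc, "foldChange")))
  w(fcTab, "fold_change.tsv")
  w(data.table::as.data.table(as.data.frame(degTable(deg))), "deg.tsv")
  w(data.table::as.data.table(as.data.frame(associationTable(assoc))),
    "association.tsv")
  cd <- colData(fc)
  w(data.table::data.table(sample_id = names(scoreValues(score)),
                           score = unname(scoreValues(score)),
                           role = cd[names(scoreValues(score)), "role"]),
    "scores.tsv")
  w(data.table::as.data.table(aucTab), "roc.tsv")
  jsonlite::write_json(
    list(threshold_I = thresholdI(thresholds),
         threshold_II = thresholdII(thresholds),
         method = thresholds@method,
         derivation = thresholds@derivation),
    file.path(outDir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  w(data.table::data.table(sample_id = rownames(predictions), predictions),
    "predictions.tsv")
  reportJson <- report[setdiff(names(report), "results")]
  reportJson$stages$roc <- as.data.frame(reportJson$stages$roc)
  reportJson$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(reportJson, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outDir)
}
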