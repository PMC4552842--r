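#' Write a cohort to a directory of tab-delimited files
#'
#' Writes \code{expression.tsv} (probe_id plus one column per sample),
#' \code{control.tsv} (probe_id, control), \code{background.tsv} (probe_id,
#' bg_mean, bg_sd; only when background statistics are present),
#' \code{flags.tsv} (probe_id plus 0/1 bad-spot columns; only when flags are
#' present), \code{metadata.tsv} (sample_id, disease, fibrosis_grade,
#' tubular_damage_grade, role) and \code{truth.json} (only for simulated
#' cohorts). All tables are tab-delimited with a header row; intensities are
#' written at full double precision so a write/read round trip is lossless
#' to ~15 significant digits.
#'
#' @param cohort a \linkS4class{KidneyArrayExperiment}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SummarizedExperiment"))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  paths <- character()
  tsv <- function(dt, name) {
    path <- file.path(dir, name)
    data.table::fwrite(dt, path, sep = "\t")
    paths <<- c(paths, path)
  }
  expr <- data.table::data.table(probe_id = rownames(cohort))
  expr <- cbind(expr, data.table::as.data.table(assay(cohort, "intensity")))
  tsv(expr, "expression.tsv")
  tsv(data.table::data.table(probe_id = rownames(cohort),
                             control = rowData(cohort)$control),
      "control.tsv")
  rd <- rowData(cohort)
  if (all(c("bg_mean", "bg_sd") %in% colnames(rd)))
    tsv(data.table::data.table(probe_id = rownames(cohort),
                               bg_mean = rd$bg_mean, bg_sd = rd$bg_sd),
        "background.tsv")
  if ("gene" %in% colnames(rd))
    tsv(data.table::data.table(probe_id = rownames(cohort), gene = rd$gene),
        "annotation.tsv")
  if ("badSpot" %in% assayNames(cohort)) {
    fl <- data.table::data.table(probe_id = rownames(cohort))
    fl <- cbind(fl, data.table::as.data.table(assay(cohort, "badSpot")))
    tsv(fl, "flags.tsv")
  }
  cd <- as.data.frame(colData(cohort))
  tsv(data.table::data.table(sample_id = rownames(cd), cd), "metadata.tsv")
  truth <- cohortTruth(cohort)
  if (!is.null(truth)) {
    path <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(marker_probe_ids = truth@markerProbeIds,
           grade_independent_up = truth@gradeIndependentUp,
           grade_independent_down = truth@gradeIndependentDown,
           undetectable_probe_ids = truth@undetectableProbeIds,
           per_sample_grades = as.data.frame(truth@perSampleGrades),
           seed = truth@seed),
      path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a cohort from a directory of tab-delimited files
#'
#' Inverse of \code{\link{writeCohort}}; accepts the same dialect for
#' user-supplied data. \code{expression.tsv}, \code{control.tsv} and
#' \code{metadata.tsv} are required; background statistics, gene annotation,
#' bad-spot flags and simulation truth are attached when the corresponding
#' files are present.
#'
#' @param dir directory containing the cohort files.
#' @return A \linkS4class{KidneyArrayExperiment}.
#' @export
readCohort <- function(dir) {
  if (!dir.exists(dir))
    stop("cohort directory not found: ", dir)
  need <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path))
      stop("missing required cohort file: ", name)
    path
  }
  expr <- data.table::fread(need("expression.tsv"), sep = "\t")
  probeIds <- expr$probe_id
  intensity <- as.matrix(expr[, -"probe_id"])
  rownames(intensity) <- probeIds

  ctl <- data.table::fread(need("control.tsv"), sep = "\t")
  control <- stats::setNames(ctl$control, ctl$probe_id)[probeIds]

  md <- data.table::fread(need("metadata.tsv"), sep = "\t")
  cd <- DataFrame(md[, -"sample_id"], row.names = md$sample_id)
  cd <- cd[colnames(intensity), , drop = FALSE]

  opt <- function(name) {
    path <- file.path(dir, name)
    if (file.exists(path)) data.table::fread(path, sep = "\t") else NULL
  }
  gene <- bgMean <- bgSd <- badSpot <- NULL
  bg <- opt("background.tsv")
  if (!is.null(bg)) {
    ord <- match(probeIds, bg$probe_id)
    bgMean <- bg$bg_mean[ord]
    bgSd <- bg$bg_sd[ord]
  }
  ann <- opt("annotation.tsv")
  if (!is.null(ann))
    gene <- ann$gene[match(probeIds, ann$probe_id)]
  fl <- opt("flags.tsv")
  if (!is.null(fl)) {
    badSpot <- as.matrix(fl[, -"probe_id"])
    rownames(badSpot) <- fl$probe_id
    badSpot <- badSpot[probeIds, colnames(intensity), drop = FALSE]
  }
  meta <- list()
  truthPath <- file.path(dir, "truth.json")
  if (file.exists(truthPath)) {
    tj <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
    meta$truth <- new("SyntheticTruth",
                      markerProbeIds = as.character(tj$marker_probe_ids),
                      gradeIndependentUp = as.character(tj$grade_independent_up),
                      gradeIndependentDown = as.character(tj$grade_independent_down),
                      undetectableProbeIds = as.character(tj$undetectable_probe_ids),
                      perSampleGrades = DataFrame(tj$per_sample_grades),
                      seed = as.integer(tj$seed))
  }
  KidneyArrayExperiment(intensity = intensity, control = control,
                        colData = cd, gene = gene, bgMean = bgMean,
                        bgSd = bgSd, badSpot = badSpot, metadata = meta)
}
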