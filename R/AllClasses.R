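#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.GRADE_MIN <- 0L
.GRADE_MAX <- 5L

#' Disease categories used in the discovery cohort
#'
#' The enumeration of primary renal diseases recognised by the package,
#' together with the subset of primary glomerulonephritis / diabetic
#' nephropathy categories conventionally used for grade-association analysis.
#'
#' @return A character vector of category codes.
#' @export
diseaseCategories <- function() {
  c("IgA nephropathy", "membranous nephropathy",
    "minimal change nephrotic syndrome",
    "membranoproliferative glomerulonephropathy",
    "diabetic nephropathy", "lupus nephritis", "amyloidosis",
    "ANCA-related glomerulonephropathy", "other")
}

#' @rdname diseaseCategories
#' @export
glomerulopathyCategories <- function() {
  c("IgA nephropathy", "membranous nephropathy",
    "minimal change nephrotic syndrome",
    "membranoproliferative glomerulonephropathy",
    "diabetic nephropathy")
}

#' Default marker gene panel
#'
#' The five-gene panel (HAVCR1/KIM-1, LCN2/NGAL, SOX9, WFDC2, NKX6-2) whose
#' geometric-mean fold change defines the molecular score.
#'
#' @return Character vector of gene symbols.
#' @export
markerPanel <- function() c("HAVCR1", "LCN2", "SOX9", "WFDC2", "NKX6-2")

# ---------------------------------------------------------------------------
# KidneyArrayExperiment
# ---------------------------------------------------------------------------

#' KidneyArrayExperiment: probe-level renal biopsy intensities
#'
#' A \linkS4class{SummarizedExperiment} holding one-color microarray
#' intensities (assay \code{"intensity"}, probes x biopsy samples), an
#' optional bad-spot flag assay (\code{"badSpot"}, 0/1), per-probe feature
#' annotation in \code{rowData} (\code{gene}, \code{bg_mean}, \code{bg_sd},
#' and the \code{control} reference profile), and per-sample metadata in
#' \code{colData} (\code{disease}, \code{fibrosis_grade},
#' \code{tubular_damage_grade}, \code{role}).
#'
#' The control profile is a single reference kidney RNA hybridisation; it is
#' carried per probe rather than as a sample column so that probe filtering
#' keeps experiment and reference aligned.
#'
#' @aliases KidneyArrayExperiment-class
#' @exportClass KidneyArrayExperiment
setClass("KidneyArrayExperiment", contains = "SummarizedExperiment")

.validKidneyArrayExperiment <- function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    x <- assay(object, "intensity")
    if (any(!is.na(x) & x <= 0))
      msg <- c(msg, "all retained intensities must be > 0")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate probe identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  rd <- rowData(object)
  if (!"control" %in% colnames(rd))
    msg <- c(msg, "rowData column 'control' (reference profile) is required")
  else if (any(!is.na(rd$control) & rd$control <= 0))
    msg <- c(msg, "control intensities must be > 0")
  cd <- colData(object)
  for (gcol in c("fibrosis_grade", "tubular_damage_grade")) {
    if (gcol %in% colnames(cd)) {
      g <- cd[[gcol]]
      bad <- !is.na(g) & (g < .GRADE_MIN | g > .GRADE_MAX | g != round(g))
      if (any(bad))
        msg <- c(msg, sprintf("%s must be integer grades in [%d, %d]",
                              gcol, .GRADE_MIN, .GRADE_MAX))
    }
  }
  if ("role" %in% colnames(cd) &&
      !all(cd$role %in% c("discovery", "validation", "control")))
    msg <- c(msg, "role must be one of discovery/validation/control")
  if (length(msg)) msg else TRUE
}
setValidity("KidneyArrayExperiment", .validKidneyArrayExperiment)

#' Construct a KidneyArrayExperiment
#'
#' @param intensity numeric matrix, probes x samples, strictly positive
#'   (NA allowed for masked cells). Must have row and column names.
#' @param control numeric vector of reference-profile intensities, one per
#'   probe (recycled by name if named).
#' @param colData data.frame/DataFrame of per-sample metadata with columns
#'   \code{disease}, \code{fibrosis_grade}, \code{tubular_damage_grade},
#'   \code{role}.
#' @param gene optional character vector of gene symbols per probe.
#' @param bgMean,bgSd optional per-probe background mean / SD.
#' @param badSpot optional 0/1 matrix of bad-spot flags, same dim as
#'   \code{intensity}.
#' @param metadata list of experiment-level metadata (e.g. simulation truth).
#' @return A \linkS4class{KidneyArrayExperiment}.
#' @export
KidneyArrayExperiment <- function(intensity, control, colData,
                                  gene = NULL, bgMean = NULL, bgSd = NULL,
                                  badSpot = NULL, metadata = list()) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    stop("intensity matrix must have probe rownames and sample colnames")
  rd <- DataFrame(row.names = rownames(intensity))
  rd$control <- if (!is.null(names(control)))
    unname(control[rownames(intensity)]) else control
  if (!is.null(gene)) rd$gene <- gene
  if (!is.null(bgMean)) rd$bg_mean <- bgMean
  if (!is.null(bgSd)) rd$bg_sd <- bgSd
  assays <- list(intensity = intensity)
  if (!is.null(badSpot)) {
    badSpot <- as.matrix(badSpot)
    stopifnot(identical(dim(badSpot), dim(intensity)))
    dimnames(badSpot) <- dimnames(intensity)
    assays$badSpot <- badSpot
  }
  se <- SummarizedExperiment(assays = assays, rowData = rd,
                             colData = as(colData, "DataFrame"),
                             metadata = metadata)
  new("KidneyArrayExperiment", se)
}

# ---------------------------------------------------------------------------
# FoldChangeProfile
# ---------------------------------------------------------------------------

#' FoldChangeProfile: per-sample unlogged ratios to the control profile
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"foldChange"}
#' (strictly positive unlogged ratios, probes x samples), per-probe
#' \code{rowData} columns \code{meanRatio} (arithmetic mean ratio over the
#' cohort samples named in \code{metadata()$meanSamples}) and
#' \code{detectable} (logical probe-level detectability), plus the sample
#' metadata inherited from the source experiment.
#'
#' @aliases FoldChangeProfile-class
#' @exportClass FoldChangeProfile
setClass("FoldChangeProfile", contains = "SummarizedExperiment")

setValidity("FoldChangeProfile", function(object) {
  msg <- character()
  if (!"foldChange" %in% assayNames(object))
    msg <- c(msg, "assay 'foldChange' is required")
  else if (any(assay(object, "foldChange") <= 0, na.rm = TRUE))
    msg <- c(msg, "fold-change ratios must be strictly positive")
  rd <- rowData(object)
  if (!all(c("meanRatio", "detectable") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'meanRatio' and 'detectable'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Result containers
# ---------------------------------------------------------------------------

#' Differential-expression result from the z-score rule
#'
#' Slots: \code{table} — a \code{DataFrame} with one row per scored probe
#' (\code{probe_id}, \code{gene}, \code{mean_ratio}, \code{log2_ratio},
#' \code{z}, \code{direction}); \code{cutoff} — the |z| cutoff used for the
#' direction labels; \code{scale} — \code{"log2"} or \code{"linear"}, the
#' scale on which ratios were standardised.
#'
#' @aliases DEGResult-class
#' @exportClass DEGResult
setClass("DEGResult",
         representation(table = "DataFrame", cutoff = "numeric",
                        scale = "character"))

#' Grade-association result from dual-endpoint Kruskal-Wallis testing
#'
#' Slots: \code{table} — \code{DataFrame} with per-probe \code{H_fibrosis},
#' \code{P_fibrosis}, \code{H_tubular}, \code{P_tubular} and the
#' \code{selected} flag (both P below alpha); \code{alpha} — significance
#' level; \code{samples} — ids of the samples the tests were run on;
#' \code{adjusted} — whether Benjamini-Hochberg adjustment was applied.
#'
#' @aliases AssociationResult-class
#' @exportClass AssociationResult
setClass("AssociationResult",
         representation(table = "DataFrame", alpha = "numeric",
                        samples = "character", adjusted = "logical"))

#' Molecular score: geometric-mean marker-panel fold change
#'
#' Slots: \code{scores} — named positive numeric, one score per sample;
#' \code{markerGenes} — the gene panel; \code{markerProbes} — the probes
#' actually averaged (all detectable probes mapping to the panel).
#'
#' @aliases MolecularScore-class
#' @exportClass MolecularScore
setClass("MolecularScore",
         representation(scores = "numeric", markerGenes = "character",
                        markerProbes = "character"))

setValidity("MolecularScore", function(object) {
  if (any(object@scores <= 0)) "scores must be strictly positive" else TRUE
})

#' ROC curve and AUC for a score against a binary grade dichotomization
#'
#' Slots: \code{thresholds}, \code{sensitivity}, \code{fpr} — the empirical
#' ROC step curve from (0,0) to (1,1); \code{auc} — tie-corrected
#' Mann-Whitney AUC; \code{endpoint} and \code{dichotomization} — labels for
#' the histopathology endpoint and grade split evaluated.
#'
#' @aliases ROCResult-class
#' @exportClass ROCResult
setClass("ROCResult",
         representation(thresholds = "numeric", sensitivity = "numeric",
                        fpr = "numeric", auc = "numeric",
                        endpoint = "character", dichotomization = "character"))

#' Score thresholds for grade-category prediction
#'
#' Slots: \code{thresholdI} — score cutoff separating grade <=2 from >=3;
#' \code{thresholdII} — cutoff separating grade <=3 from >=4 (never below
#' Threshold I; the ordering is enforced and recorded when binding);
#' \code{method} — derivation method (\code{"youden"} or
#' \code{"max-accuracy"}); \code{derivation} — list recording endpoints,
#' discovery sample ids and whether the ordering constraint was binding.
#'
#' @aliases GradeThresholds-class
#' @exportClass GradeThresholds
setClass("GradeThresholds",
         representation(thresholdI = "numeric", thresholdII = "numeric",
                        method = "character", derivation = "list"))

setValidity("GradeThresholds", function(object) {
  msg <- character()
  if (object@thresholdI <= 0 || object@thresholdII <= 0)
    msg <- c(msg, "thresholds must be positive")
  if (object@thresholdII < object@thresholdI)
    msg <- c(msg, "thresholdII must be >= thresholdI")
  if (length(msg)) msg else TRUE
})

#' Planted structure of a synthetic cohort
#'
#' Records exactly what the generator planted so recovery is checkable:
#' marker probes (grade-driven), grade-independent up/down-shifted probes,
#' probes planted at background level (undetectable), the per-sample grade
#' pairs, and the seed.
#'
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(markerProbeIds = "character",
                        gradeIndependentUp = "character",
                        gradeIndependentDown = "character",
                        undetectableProbeIds = "character",
                        perSampleGrades = "DataFrame",
                        seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  shifted <- c(object@gradeIndependentUp, object@gradeIndependentDown)
  if (length(intersect(object@markerProbeIds, shifted)))
    "marker probes must be disjoint from grade-independent shifted probes"
  else TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "DEGResult", function(object) {
  tab <- table(factor(object@table$direction,
                      levels = c("up", "down", "unchanged")))
  cat(sprintf(
    "DEGResult: %d probes standardised on %s scale (|z| cutoff %.2f)\n",
    nrow(object@table), object@scale, object@cutoff))
  cat(sprintf("  up %d / down %d / unchanged %d\n",
              tab[["up"]], tab[["down"]], tab[["unchanged"]]))
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf(
    "AssociationResult: %d candidate probes, %d samples, alpha = %g%s\n",
    nrow(object@table), length(object@samples), object@alpha,
    if (object@adjusted) " (BH-adjusted)" else ""))
  cat(sprintf("  significant: fibrosis %d, tubular %d, both %d\n",
              sum(object@table$P_fibrosis < object@alpha),
              sum(object@table$P_tubular < object@alpha),
              sum(object@table$selected)))
})

setMethod("show", "MolecularScore", function(object) {
  cat(sprintf(
    "MolecularScore: %d samples, %d marker genes over %d probes\n",
    length(object@scores), length(object@markerGenes),
    length(object@markerProbes)))
  cat("  range:", sprintf("%.3g", min(object@scores)), "-",
      sprintf("%.3g", max(object@scores)), "\n")
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult [%s, %s]: AUC = %s (%d curve points)\n",
              object@endpoint, object@dichotomization,
              ifelse(is.na(object@auc), "undefined",
                     sprintf("%.3f", object@auc)),
              length(object@sensitivity)))
})

setMethod("show", "GradeThresholds", function(object) {
  cat(sprintf(
    "GradeThresholds (%s): Threshold I = %.4g (grade >=3), Threshold II = %.4g (grade >=4)\n",
    object@method, object@thresholdI, object@thresholdII))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth (seed %d): %d marker probes, %d/%d grade-independent up/down, %d undetectable, %d samples\n",
    object@seed, length(object@markerProbeIds),
    length(object@gradeIndependentUp), length(object@gradeIndependentDown),
    length(object@undetectableProbeIds), nrow(object@perSampleGrades)))
})
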