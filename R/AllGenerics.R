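# Accessor generics for the package's result classes.

#' @rdname accessors
#' @export
setGeneric("controlProfile", function(x) standardGeneric("controlProfile"))

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname accessors
#' @export
setGeneric("degTable", function(x) standardGeneric("degTable"))

#' @rdname accessors
#' @export
setGeneric("associationTable", function(x) standardGeneric("associationTable"))

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname accessors
#' @export
setGeneric("markerProbes", function(x) standardGeneric("markerProbes"))

#' @rdname accessors
#' @export
setGeneric("markerGenes", function(x) standardGeneric("markerGenes"))

#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname accessors
#' @export
setGeneric("thresholdI", function(x) standardGeneric("thresholdI"))

#' @rdname accessors
#' @export
setGeneric("thresholdII", function(x) standardGeneric("thresholdII"))

#' Accessors for ckdms result objects
#'
#' \code{controlProfile} returns the per-probe reference intensities;
#' \code{cohortTruth} the planted \linkS4class{SyntheticTruth} of a simulated
#' cohort (or NULL); \code{degTable} / \code{associationTable} the per-probe
#' result tables; \code{scoreValues}, \code{markerProbes}, \code{markerGenes}
#' the contents of a \linkS4class{MolecularScore}; \code{aucValue} the AUC of
#' a \linkS4class{ROCResult}; \code{thresholdI} / \code{thresholdII} the
#' score cutoffs of a \linkS4class{GradeThresholds}.
#'
#' @param x a ckdms object.
#' @return The component named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("controlProfile", "SummarizedExperiment", function(x) {
  ctl <- rowData(x)$control
  if (is.null(ctl)) stop("no control profile in rowData")
  stats::setNames(ctl, rownames(x))
})

#' @rdname accessors
#' @export
setMethod("cohortTruth", "SummarizedExperiment",
          function(x) S4Vectors::metadata(x)$truth)

#' @rdname accessors
#' @export
setMethod("degTable", "DEGResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("associationTable", "AssociationResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("scoreValues", "MolecularScore", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("markerProbes", "MolecularScore", function(x) x@markerProbes)

#' @rdname accessors
#' @export
setMethod("markerGenes", "MolecularScore", function(x) x@markerGenes)

#' @rdname accessors
#' @export
setMethod("aucValue", "ROCResult", function(x) x@auc)

#' @rdname accessors
#' @export
setMethod("thresholdI", "GradeThresholds", function(x) x@thresholdI)

#' @rdname accessors
#' @export
setMethod("thresholdII", "GradeThresholds", function(x) x@thresholdII)
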