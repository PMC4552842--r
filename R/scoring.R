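#' Molecular score: geometric-mean marker-panel fold change
#'
#' Per sample, the geometric mean of the unlogged fold changes of all
#' detectable probes mapping to the marker genes, computed in log space for
#' numerical stability (identical to the product-root form). A score of 1
#' means marker expression at control level.
#'
#' @param fc a \linkS4class{FoldChangeProfile} with a \code{gene} column in
#'   \code{rowData}.
#' @param genes marker gene symbols (default the
#'   HAVCR1/LCN2/SOX9/WFDC2/NKX6-2 panel).
#' @param samples sample ids to score (default: all samples).
#' @return A \linkS4class{MolecularScore}.
#' @examples
#' \dontrun{
#' score <- molecularScore(fc)          # all samples, default panel
#' scoreValues(score)
#' }
#' @export
molecularScore <- function(fc, genes = markerPanel(), samples = NULL) {
  stopifnot(is(fc, "FoldChangeProfile"))
  rd <- rowData(fc)
  if (!"gene" %in% colnames(rd))
    stop("fold-change profile carries no gene annotation")
  if (is.null(samples)) samples <- colnames(fc)
  stopifnot(all(samples %in% colnames(fc)))
  probes <- character()
  for (g in genes) {
    pg <- rownames(fc)[rd$gene == g & rd$detectable]
    if (!length(pg))
      stop("marker gene has no detectable probes: ", g)
    probes <- c(probes, pg)
  }
  ratios <- assay(fc, "foldChange")[probes, samples, drop = FALSE]
  scores <- exp(colMeans(log(ratios)))
  new("MolecularScore", scores = scores, markerGenes = genes,
      markerProbes = probes)
}

#' ROC curve and tie-corrected AUC
#'
#' AUC by the tie-corrected rank (Mann-Whitney) formulation: the
#' probability that a random positive outscores a random negative, ties
#' credited 1/2; equal to the trapezoidal area under the empirical ROC step
#' curve. The curve steps from (0,0) to (1,1) over the distinct score
#' cutoffs (prediction positive when score > cutoff).
#'
#' @param scores numeric scores (a \linkS4class{MolecularScore} is
#'   accepted).
#' @param labels logical (or 0/1) class labels, TRUE = positive; both
#'   classes must be present.
#' @param endpoint,dichotomization descriptive labels carried in the
#'   result.
#' @return A \linkS4class{ROCResult}.
#' @export
rocAuc <- function(scores, labels, endpoint = "score",
                   dichotomization = "binary") {
  if (is(scores, "MolecularScore")) scores <- scoreValues(scores)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an ROC curve")
  r <- rank(scores)                      # midranks handle ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(cuts, function(t) mean(scores[labels] > t), 0)
  fpr <- vapply(cuts, function(t) mean(scores[!labels] > t), 0)
  new("ROCResult", thresholds = c(Inf, cuts, -Inf),
      sensitivity = c(0, sens, 1), fpr = c(0, fpr, 1), auc = auc,
      endpoint = endpoint, dichotomization = dichotomization)
}

.dichotLabel <- function(cut) sprintf("<=%d vs >=%d", cut, cut + 1L)

#' AUC over grade dichotomizations
#'
#' For each histopathology endpoint (fibrosis, tubular damage) and each
#' grade cut \code{g} in \code{cuts}, the AUC of the score for classifying
#' grade > g versus grade <= g, plus a composite AUC per cut on pooled
#' labels (each sample contributes one labelled instance per endpoint).
#' Cells whose dichotomization leaves a single class are reported as
#' \code{NA} (undefined), not as an error. The default cuts 1, 2, 3 cover
#' the grade-1-4 discovery range: "1 vs 2-4", "1-2 vs 3-4", "1-3 vs 4".
#'
#' @param score a \linkS4class{MolecularScore} (or named numeric scores).
#' @param metadata DataFrame/data.frame of sample metadata with
#'   \code{fibrosis_grade} and \code{tubular_damage_grade}, rownames =
#'   sample ids; only samples present in \code{score} are used.
#' @param cuts integer grade cut points (default c(1, 2, 3)).
#' @return A data.frame with columns \code{endpoint} (fibrosis, tubular,
#'   composite), \code{cut}, \code{dichotomization} and \code{auc}.
#' @export
gradeDichotomizationAuc <- function(score, metadata, cuts = c(1L, 2L, 3L)) {
  s <- if (is(score, "MolecularScore")) scoreValues(score) else score
  ids <- intersect(names(s), rownames(metadata))
  if (!length(ids)) stop("no scored samples present in metadata")
  s <- s[ids]
  gF <- metadata[ids, "fibrosis_grade"]
  gT <- metadata[ids, "tubular_damage_grade"]
  safeAuc <- function(x, lab, ep, cut) {
    if (length(unique(lab)) < 2L) return(NA_real_)
    aucValue(rocAuc(x, lab, endpoint = ep,
                    dichotomization = .dichotLabel(cut)))
  }
  rows <- list()
  for (cut in as.integer(cuts)) {
    rows[[length(rows) + 1L]] <- data.frame(
      endpoint = c("fibrosis", "tubular", "composite"), cut = cut,
      dichotomization = .dichotLabel(cut),
      auc = c(safeAuc(s, gF > cut, "fibrosis", cut),
              safeAuc(s, gT > cut, "tubular", cut),
              safeAuc(c(s, s), c(gF > cut, gT > cut), "composite", cut)))
  }
  do.call(rbind, rows)
}

# Youden / accuracy scan over candidate cutoffs (midpoints between adjacent
# distinct scores, plus sentinels below the minimum and above the maximum).
# Positive prediction is score > cutoff. Among criterion maximizers the
# smallest cutoff (highest sensitivity) is chosen, deterministically.
.scanThreshold <- function(scores, labels, method = "youden") {
  u <- sort(unique(scores))
  candidates <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                  u[length(u)] + 1)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  crit <- vapply(candidates, function(t) {
    sens <- sum(scores[labels] > t) / n1
    spec <- sum(scores[!labels] <= t) / n0
    if (method == "youden") sens + spec - 1
    else (sens * n1 + spec * n0) / (n1 + n0)
  }, 0)
  candidates[which.max(crit)]   # ties: first = smallest cutoff
}

#' Derive grade thresholds from discovery scores
#'
#' Threshold I is the score cutoff separating histopathology grade <= 2
#' from >= 3; Threshold II separates <= 3 from >= 4. Each is the
#' Youden-optimal cutoff (sensitivity + specificity - 1 maximized; a
#' maximum-accuracy alternative is available) over pooled-endpoint labels:
#' every discovery sample contributes one labelled instance per endpoint.
#' Cutoffs fall midway between adjacent observed scores. Threshold II is
#' never allowed below Threshold I; when the constraint binds it is
#' recorded in the derivation.
#'
#' @param score a \linkS4class{MolecularScore} of discovery samples (or
#'   named numeric).
#' @param metadata sample metadata as in
#'   \code{\link{gradeDichotomizationAuc}}.
#' @param method \code{"youden"} (default) or \code{"max-accuracy"}.
#' @param endpoints which grade endpoints to pool (default both).
#' @return A \linkS4class{GradeThresholds}.
#' @export
deriveThresholds <- function(score, metadata,
                             method = c("youden", "max-accuracy"),
                             endpoints = c("fibrosis", "tubular")) {
  method <- match.arg(method)
  s <- if (is(score, "MolecularScore")) scoreValues(score) else score
  ids <- intersect(names(s), rownames(metadata))
  if (length(ids) < 2L) stop("need at least 2 scored discovery samples")
  s <- s[ids]
  grades <- list(fibrosis = metadata[ids, "fibrosis_grade"],
                 tubular = metadata[ids, "tubular_damage_grade"])[endpoints]
  pooledScores <- rep(s, length(grades))
  pooledGrades <- unlist(grades, use.names = FALSE)
  fitOne <- function(cut) {
    labels <- pooledGrades > cut
    if (!any(labels) || all(labels))
      stop(sprintf(
        "single-class dichotomization at grade cut %d; cannot derive threshold",
        cut))
    .scanThreshold(pooledScores, labels, method)
  }
  tI <- fitOne(2L)
  tII <- fitOne(3L)
  binding <- tII < tI
  if (binding) tII <- tI
  new("GradeThresholds", thresholdI = tI, thresholdII = tII,
      method = method,
      derivation = list(endpoints = endpoints, samples = ids,
                        orderingConstraintBinding = binding))
}

#' Predict grade categories from a molecular score
#'
#' A sample is predicted grade >= 3 when its score strictly exceeds
#' Threshold I, and grade >= 4 when it strictly exceeds Threshold II; a
#' score exactly at a threshold stays in the lower category.
#'
#' @param score numeric score(s) or a \linkS4class{MolecularScore}.
#' @param thresholds a \linkS4class{GradeThresholds}.
#' @return A data.frame with columns \code{score}, \code{category_I}
#'   (\code{"<=2"} / \code{">=3"}) and \code{category_II} (\code{"<=3"} /
#'   \code{">=4"}).
#' @export
predictGradeCategory <- function(score, thresholds) {
  stopifnot(is(thresholds, "GradeThresholds"))
  s <- if (is(score, "MolecularScore")) scoreValues(score) else score
  data.frame(row.names = names(s), score = unname(s),
             category_I = ifelse(s > thresholds@thresholdI, ">=3", "<=2"),
             category_II = ifelse(s > thresholds@thresholdII, ">=4", "<=3"))
}

#' Score and classify a validation cohort
#'
#' Scores the validation samples with the same marker probes and control
#' profile as the discovery set, applies the discovery-derived thresholds,
#' and flags concordance between each predicted category and the observed
#' grade of each endpoint: a prediction is concordant when the observed
#' grade falls in the predicted category.
#'
#' @param fc a \linkS4class{FoldChangeProfile} containing the validation
#'   samples (computed against the same control as discovery).
#' @param thresholds a \linkS4class{GradeThresholds} from the discovery
#'   set.
#' @param genes marker panel (default \code{\link{markerPanel}}).
#' @param samples validation sample ids; default all samples with role
#'   \code{"validation"}. An empty set yields an empty table.
#' @param markerProbes optional explicit probe set (e.g. from the
#'   discovery \linkS4class{MolecularScore}) — an error is raised if any
#'   are absent, guarding against probe-set mismatch between cohorts.
#' @return A data.frame with one row per validation sample: \code{score},
#'   \code{category_I}, \code{category_II}, observed grades, and
#'   \code{concordant_I_fibrosis}, \code{concordant_I_tubular},
#'   \code{concordant_II_fibrosis}, \code{concordant_II_tubular}.
#' @export
validateCohort <- function(fc, thresholds, genes = markerPanel(),
                           samples = NULL, markerProbes = NULL) {
  stopifnot(is(fc, "FoldChangeProfile"), is(thresholds, "GradeThresholds"))
  if (is.null(samples))
    samples <- colnames(fc)[colData(fc)$role == "validation"]
  empty <- data.frame(score = numeric(), category_I = character(),
                      category_II = character(),
                      fibrosis_grade = integer(),
                      tubular_damage_grade = integer(),
                      concordant_I_fibrosis = logical(),
                      concordant_I_tubular = logical(),
                      concordant_II_fibrosis = logical(),
                      concordant_II_tubular = logical())
  if (!length(samples)) return(empty)
  if (!is.null(markerProbes) && !all(markerProbes %in% rownames(fc)))
    stop("probe-set mismatch: marker probes absent from validation profile: ",
         paste(setdiff(markerProbes, rownames(fc)), collapse = ", "))
  ms <- molecularScore(fc, genes = genes, samples = samples)
  if (!is.null(markerProbes) &&
      !setequal(markerProbes, markerProbes(ms)))
    stop("probe-set mismatch between discovery and validation scoring")
  pred <- predictGradeCategory(ms, thresholds)
  cd <- colData(fc)[samples, , drop = FALSE]
  gF <- cd$fibrosis_grade
  gT <- cd$tubular_damage_grade
  cbind(pred,
        data.frame(fibrosis_grade = gF, tubular_damage_grade = gT,
                   concordant_I_fibrosis = (gF >= 3) == (pred$category_I == ">=3"),
                   concordant_I_tubular = (gT >= 3) == (pred$category_I == ">=3"),
                   concordant_II_fibrosis = (gF >= 4) == (pred$category_II == ">=4"),
                   concordant_II_tubular = (gT >= 4) == (pred$category_II == ">=4"),
                   row.names = rownames(pred)))
}
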