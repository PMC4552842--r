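#' Drop bad spots and impute masked cells
#'
#' Flagged cells are set to missing before normalization. Probes whose
#' missing fraction exceeds \code{maxMissingFraction} are dropped; remaining
#' missing cells are imputed by the probe median across samples (a simple,
#' rank-preserving fill; downstream grade tests are rank-based).
#'
#' @param x a \linkS4class{KidneyArrayExperiment}; if it carries no
#'   \code{badSpot} assay the input is returned unchanged.
#' @param maxMissingFraction drop a probe when its flagged fraction of
#'   samples exceeds this value (default 0.2).
#' @return A \linkS4class{KidneyArrayExperiment} without a \code{badSpot}
#'   assay.
#' @export
dropBadSpots <- function(x, maxMissingFraction = 0.2) {
  stopifnot(is(x, "SummarizedExperiment"))
  if (!"badSpot" %in% assayNames(x))
    return(x)
  intensity <- assay(x, "intensity")
  flags <- assay(x, "badSpot") != 0
  intensity[flags] <- NA_real_
  missFrac <- rowMeans(is.na(intensity))
  keep <- missFrac <= maxMissingFraction
  if (!any(keep))
    stop("all probes dropped by the bad-spot rule")
  intensity <- intensity[keep, , drop = FALSE]
  probeMed <- apply(intensity, 1, stats::median, na.rm = TRUE)
  na <- which(is.na(intensity), arr.ind = TRUE)
  if (nrow(na))
    intensity[na] <- probeMed[na[, 1]]
  out <- x[keep, ]
  assays(out) <- list(intensity = intensity)
  out
}

#' Median-normalize arrays
#'
#' Rescales each array multiplicatively so that its median intensity equals
#' a common target. The control profile is rescaled the same way so that
#' fold changes compare like with like. The default target is the grand
#' median of all per-array medians (control included), which makes the
#' operation idempotent.
#'
#' @param x a \linkS4class{KidneyArrayExperiment}.
#' @param target positive scalar, or \code{"global"} for the grand median of
#'   the per-array medians.
#' @return The normalized experiment.
#' @export
medianNormalize <- function(x, target = "global") {
  stopifnot(is(x, "SummarizedExperiment"))
  intensity <- assay(x, "intensity")
  control <- rowData(x)$control
  med <- apply(intensity, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med) | med <= 0))
    stop("every sample must have at least one positive intensity")
  ctlMed <- stats::median(control, na.rm = TRUE)
  if (identical(target, "global")) {
    target <- stats::median(c(med, ctlMed))
  } else {
    if (!is.numeric(target) || length(target) != 1L || target <= 0)
      stop("target: must be a positive scalar or \"global\"")
  }
  intensity <- sweep(intensity, 2, target / med, "*")
  assay(x, "intensity") <- intensity
  rowData(x)$control <- control * (target / ctlMed)
  x
}

#' Detectability filter against feature background
#'
#' A probe is detectable in a sample when its signal exceeds the feature
#' background mean and the one-sided z statistic
#' \code{(intensity - bg_mean) / bg_sd} exceeds the upper-\code{alpha}
#' normal quantile. A probe is retained overall when it is detectable in at
#' least \code{minFraction} of the samples.
#'
#' @param x a \linkS4class{KidneyArrayExperiment} with \code{bg_mean} and
#'   \code{bg_sd} in \code{rowData}.
#' @param alpha one-sided significance level (default 0.05).
#' @param minFraction retention quorum across samples (default 0.5).
#' @return A list with \code{cellDetectable} (logical probe x sample matrix)
#'   and \code{probeDetectable} (named logical vector).
#' @export
filterDetectable <- function(x, alpha = 0.05, minFraction = 0.5) {
  stopifnot(is(x, "SummarizedExperiment"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha: must be in (0, 1)")
  rd <- rowData(x)
  if (!all(c("bg_mean", "bg_sd") %in% colnames(rd)))
    stop("background statistics (bg_mean, bg_sd) are required ",
         "for the detectability filter")
  intensity <- assay(x, "intensity")
  z <- (intensity - rd$bg_mean) / rd$bg_sd
  cell <- (intensity > rd$bg_mean) & (z > stats::qnorm(1 - alpha))
  probe <- rowMeans(cell) >= minFraction
  names(probe) <- rownames(x)
  list(cellDetectable = cell, probeDetectable = probe)
}

#' Fold change versus the control kidney profile
#'
#' Per-probe, per-sample unlogged ratio of the sample intensity to the
#' control-profile intensity, with the denominator floored to avoid
#' division blow-ups at near-background control values, plus the per-probe
#' cohort-mean ratio (arithmetic mean over the cohort samples, by default
#' the discovery set).
#'
#' @param x a \linkS4class{KidneyArrayExperiment}.
#' @param floor positive scalar; control intensities below it are replaced
#'   by it. Default: the 1st percentile of the control intensities.
#' @param meanSamples sample ids over which the cohort-mean ratio is taken;
#'   default all samples with role \code{"discovery"} (or all samples when
#'   no role column is present).
#' @param detectable optional named logical vector of probe-level
#'   detectability (from \code{\link{filterDetectable}}); recorded in
#'   \code{rowData} and defaulting to all-\code{TRUE}.
#' @return A \linkS4class{FoldChangeProfile}.
#' @export
computeFoldChange <- function(x, floor = NULL, meanSamples = NULL,
                              detectable = NULL) {
  stopifnot(is(x, "SummarizedExperiment"))
  intensity <- assay(x, "intensity")
  control <- rowData(x)$control
  missing <- is.na(control)
  if (any(missing))
    stop("control profile missing for probes: ",
         paste(utils::head(rownames(x)[missing], 5), collapse = ", "),
         if (sum(missing) > 5) sprintf(" (and %d more)", sum(missing) - 5))
  if (is.null(floor))
    floor <- stats::quantile(control, 0.01, names = FALSE)
  if (!is.numeric(floor) || floor <= 0)
    stop("floor: must be a positive scalar")
  denom <- pmax(control, floor)
  ratio <- intensity / denom
  if (is.null(meanSamples)) {
    meanSamples <- if ("role" %in% colnames(colData(x)))
      colnames(x)[colData(x)$role == "discovery"] else colnames(x)
  }
  if (!length(meanSamples) || !all(meanSamples %in% colnames(x)))
    stop("meanSamples must name samples present in the experiment")
  meanRatio <- rowMeans(ratio[, meanSamples, drop = FALSE])
  det <- if (is.null(detectable)) {
    stats::setNames(rep(TRUE, nrow(x)), rownames(x))
  } else {
    stopifnot(all(rownames(x) %in% names(detectable)))
    detectable[rownames(x)]
  }
  rd <- rowData(x)
  rd$meanRatio <- meanRatio
  rd$detectable <- unname(det)
  se <- SummarizedExperiment(assays = list(foldChange = ratio),
                             rowData = rd, colData = colData(x),
                             metadata = c(S4Vectors::metadata(x),
                                          list(floor = floor,
                                               meanSamples = meanSamples)))
  new("FoldChangeProfile", se)
}
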