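#' Simulation parameters for synthetic renal-biopsy cohorts
#'
#' Parameter container for \code{\link{generateCohort}}. Defaults emulate the
#' study design the pipeline targets: a 48-biopsy discovery set plus a
#' 5-biopsy validation set over 20,000 probes, with a small panel of marker
#' genes whose log2 expression rises linearly with the tubular-damage grade,
#' a sprinkling of grade-independent up/down-shifted probes, multiplicative
#' log-normal measurement noise, and per-feature background statistics with
#' planted bad spots and undetectable features so the preprocessing filters
#' have real work to do.
#'
#' @param nProbes number of array probes (default 20000).
#' @param nMarkerGenes number of grade-driven marker genes (default 5).
#' @param probesPerMarkerGene probes per marker gene (default 2).
#' @param nDiscovery discovery-set size (default 48).
#' @param nValidation validation-set size (default 5).
#' @param gradeRange integer pair in [0, 5]; grades are drawn uniformly over
#'   this range (default c(1, 4), the discovery-set range).
#' @param effectSlopeLog2 log2 fold-change increase of marker genes per unit
#'   of tubular-damage grade (default 0.8); 0 gives the null model.
#' @param backgroundDeFraction fraction of non-marker probes given a
#'   grade-independent up or down shift (default 0.02).
#' @param noiseSdLog2 per-observation log2 noise SD (default 0.5).
#' @param baselineLog2Mean,baselineLog2Sd log-normal baseline intensity
#'   parameters on the log2 scale (defaults 8 and 1.5).
#' @param badSpotFraction fraction of sample cells flagged as bad spots and
#'   corrupted (default 0.01).
#' @param undetectableFraction fraction of probes planted at background level
#'   (default 0.05).
#' @param gradeCorrelation target Spearman rank correlation between the
#'   fibrosis and tubular-damage grades (default 0.8). The two grades are
#'   generated from a Gaussian copula whose latent correlation is calibrated
#'   so the discretized grades attain this rank correlation.
#' @param markerGeneNames symbols assigned to the marker genes; defaults to
#'   the HAVCR1/LCN2/SOX9/WFDC2/NKX6-2 panel, extended with MKxxx names when
#'   \code{nMarkerGenes > 5}.
#' @param seed integer RNG seed.
#' @return A \code{SimulationParams} object.
#' @export
simulationParams <- function(nProbes = 20000L, nMarkerGenes = 5L,
                             probesPerMarkerGene = 2L, nDiscovery = 48L,
                             nValidation = 5L, gradeRange = c(1L, 4L),
                             effectSlopeLog2 = 0.8,
                             backgroundDeFraction = 0.02,
                             noiseSdLog2 = 0.5, baselineLog2Mean = 8,
                             baselineLog2Sd = 1.5, badSpotFraction = 0.01,
                             undetectableFraction = 0.05,
                             gradeCorrelation = 0.8,
                             markerGeneNames = NULL, seed = 1L) {
  if (is.null(markerGeneNames)) {
    markerGeneNames <- markerPanel()
    if (nMarkerGenes > length(markerGeneNames))
      markerGeneNames <- c(markerGeneNames,
                           sprintf("MK%03d", seq_len(nMarkerGenes - 5L) + 5L))
    markerGeneNames <- markerGeneNames[seq_len(max(nMarkerGenes, 0L))]
  }
  new("SimulationParams",
      nProbes = as.integer(nProbes), nMarkerGenes = as.integer(nMarkerGenes),
      probesPerMarkerGene = as.integer(probesPerMarkerGene),
      nDiscovery = as.integer(nDiscovery),
      nValidation = as.integer(nValidation),
      gradeRange = as.integer(gradeRange),
      effectSlopeLog2 = effectSlopeLog2,
      backgroundDeFraction = backgroundDeFraction,
      noiseSdLog2 = noiseSdLog2, baselineLog2Mean = baselineLog2Mean,
      baselineLog2Sd = baselineLog2Sd, badSpotFraction = badSpotFraction,
      undetectableFraction = undetectableFraction,
      gradeCorrelation = gradeCorrelation,
      markerGeneNames = markerGeneNames, seed = as.integer(seed))
}

#' @aliases SimulationParams-class
#' @rdname simulationParams
#' @exportClass SimulationParams
setClass("SimulationParams",
         representation(nProbes = "integer", nMarkerGenes = "integer",
                        probesPerMarkerGene = "integer",
                        nDiscovery = "integer", nValidation = "integer",
                        gradeRange = "integer", effectSlopeLog2 = "numeric",
                        backgroundDeFraction = "numeric",
                        noiseSdLog2 = "numeric", baselineLog2Mean = "numeric",
                        baselineLog2Sd = "numeric",
                        badSpotFraction = "numeric",
                        undetectableFraction = "numeric",
                        gradeCorrelation = "numeric",
                        markerGeneNames = "character", seed = "integer"))

setValidity("SimulationParams", function(object) {
  msg <- character()
  chk <- function(cond, field, what)
    if (!cond) msg <<- c(msg, sprintf("%s: %s", field, what))
  chk(object@nProbes >= 1L, "nProbes", "must be a positive integer")
  chk(object@nMarkerGenes >= 0L, "nMarkerGenes", "must be non-negative")
  chk(object@probesPerMarkerGene >= 1L, "probesPerMarkerGene",
      "must be a positive integer")
  chk(object@nDiscovery >= 1L, "nDiscovery", "must be a positive integer")
  chk(object@nValidation >= 0L, "nValidation", "must be non-negative")
  chk(length(object@gradeRange) == 2L &&
      all(object@gradeRange >= .GRADE_MIN & object@gradeRange <= .GRADE_MAX) &&
      object@gradeRange[1] <= object@gradeRange[2],
      "gradeRange", "must be an ordered integer pair within [0, 5]")
  chk(object@effectSlopeLog2 >= 0, "effectSlopeLog2", "must be >= 0")
  chk(object@backgroundDeFraction >= 0 && object@backgroundDeFraction < 1,
      "backgroundDeFraction", "must be in [0, 1)")
  chk(object@noiseSdLog2 > 0, "noiseSdLog2", "must be > 0")
  chk(object@badSpotFraction >= 0 && object@badSpotFraction < 1,
      "badSpotFraction", "must be in [0, 1)")
  chk(object@undetectableFraction >= 0 && object@undetectableFraction < 1,
      "undetectableFraction", "must be in [0, 1)")
  chk(object@gradeCorrelation >= 0 && object@gradeCorrelation <= 1,
      "gradeCorrelation", "must be in [0, 1]")
  chk(object@nMarkerGenes * object@probesPerMarkerGene <= object@nProbes,
      "nMarkerGenes", "nMarkerGenes * probesPerMarkerGene must be <= nProbes")
  chk(length(object@markerGeneNames) == object@nMarkerGenes &&
      !anyDuplicated(object@markerGeneNames),
      "markerGeneNames", "must be nMarkerGenes unique symbols")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(
    "SimulationParams: %d probes, %d+%d samples, %d marker genes x %d probes\n",
    object@nProbes, object@nDiscovery, object@nValidation,
    object@nMarkerGenes, object@probesPerMarkerGene))
  cat(sprintf(
    "  slope %.3g log2/grade, noise SD %.3g, grades U[%d,%d], rank cor %.2f, seed %d\n",
    object@effectSlopeLog2, object@noiseSdLog2, object@gradeRange[1],
    object@gradeRange[2], object@gradeCorrelation, object@seed))
})

# Standard bivariate normal CDF P(X <= a, Y <= b) with correlation rho,
# by one-dimensional quadrature; accurate enough for copula calibration.
.pbinorm <- function(a, b, rho) {
  if (a == -Inf || b == -Inf) return(0)
  if (a == Inf) return(stats::pnorm(b))
  if (b == Inf) return(stats::pnorm(a))
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((b - rho * x) / s)
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# Population Spearman correlation of two grades obtained by equal-probability
# discretization of a latent bivariate normal with correlation rho into k
# levels (Pearson correlation of midrank scores).
.discretizedSpearman <- function(rho, k) {
  if (k == 1L) return(0)
  cuts <- stats::qnorm(seq_len(k - 1L) / k)
  cdf <- c(-Inf, cuts, Inf)
  Fcum <- seq(0, 1, length.out = k + 1L)
  mid <- (Fcum[-1] + Fcum[-(k + 1L)]) / 2      # midrank score per level
  Pc <- outer(cdf, cdf, Vectorize(function(a, b) .pbinorm(a, b, rho)))
  cell <- Pc[-1, -1] - Pc[-(k + 1L), -1] - Pc[-1, -(k + 1L)] +
    Pc[-(k + 1L), -(k + 1L)]
  mu <- sum(mid * rowSums(cell))
  v <- sum(mid^2 * rowSums(cell)) - mu^2
  cv <- sum(outer(mid, mid) * cell) - mu^2
  cv / v
}

# Latent Gaussian-copula correlation that yields the target Spearman rank
# correlation after discretization into k uniform levels.
.calibrateLatentRho <- function(targetSpearman, k) {
  if (k == 1L || targetSpearman <= 0) return(0)
  upper <- 0.999999
  if (.discretizedSpearman(upper, k) <= targetSpearman) return(1)
  stats::uniroot(function(r) .discretizedSpearman(r, k) - targetSpearman,
                 interval = c(0, upper), tol = 1e-6)$root
}

.discoveryDiseaseCounts <- c(
  "IgA nephropathy" = 15L, "membranous nephropathy" = 7L,
  "minimal change nephrotic syndrome" = 4L,
  "membranoproliferative glomerulonephropathy" = 3L,
  "diabetic nephropathy" = 2L, "lupus nephritis" = 6L, "amyloidosis" = 3L,
  "ANCA-related glomerulonephropathy" = 2L, "other" = 6L)

.drawDiseases <- function(n) {
  cats <- names(.discoveryDiseaseCounts)
  if (n == sum(.discoveryDiseaseCounts))
    sample(rep(cats, .discoveryDiseaseCounts))
  else
    sample(cats, n, replace = TRUE,
           prob = .discoveryDiseaseCounts / sum(.discoveryDiseaseCounts))
}

#' Generate a synthetic renal-biopsy cohort
#'
#' Draws a probe x sample intensity matrix, a single control-kidney
#' reference profile, per-feature background statistics, bad-spot flags and
#' per-sample metadata, with planted structure recorded in a
#' \linkS4class{SyntheticTruth} object. Marker-gene probes have expected
#' log2 ratio to the control equal to \code{effectSlopeLog2 x
#' tubular_damage_grade}; the fibrosis grade is a correlated ordinal drawn
#' from a Gaussian copula. Grade-independent "background" differential
#' probes receive a fixed log2 shift (magnitude uniform on [1, 2], sign by
#' set) in every biopsy. The control profile is the noiseless baseline
#' expectation plus one measurement-noise draw, matching a single reference
#' RNA hybridisation. Fully reproducible from \code{params@seed}.
#'
#' @param params a \code{\link{simulationParams}} object.
#' @return A \linkS4class{KidneyArrayExperiment}; the planted truth is
#'   available via \code{\link{cohortTruth}}.
#' @examples
#' cohort <- generateCohort(simulationParams(nProbes = 500, seed = 7))
#' cohortTruth(cohort)
#' @export
generateCohort <- function(params = simulationParams()) {
  validObject(params)
  set.seed(params@seed)
  p <- params@nProbes
  nD <- params@nDiscovery
  nV <- params@nValidation
  n <- nD + nV
  probeIds <- sprintf("A_%06d", seq_len(p))
  nMarkerProbes <- params@nMarkerGenes * params@probesPerMarkerGene
  markerProbeIdx <- seq_len(nMarkerProbes)
  gene <- sprintf("GENE%06d", seq_len(p))
  if (nMarkerProbes > 0)
    gene[markerProbeIdx] <- rep(params@markerGeneNames,
                                each = params@probesPerMarkerGene)

  baseline <- stats::rnorm(p, params@baselineLog2Mean, params@baselineLog2Sd)
  bgMean <- 2^stats::rnorm(p, 4, 0.3)
  bgSd <- bgMean * 0.2

  nonMarker <- setdiff(seq_len(p), markerProbeIdx)
  nUndet <- round(params@undetectableFraction * p)
  undetIdx <- sort(sample(nonMarker, min(nUndet, length(nonMarker))))
  # planted at background level: mean signal below feature background
  baseline[undetIdx] <- log2(bgMean[undetIdx]) - 1

  deEligible <- setdiff(nonMarker, undetIdx)
  nDe <- round(params@backgroundDeFraction * length(nonMarker))
  deIdx <- sort(sample(deEligible, min(nDe, length(deEligible))))
  upIdx <- deIdx[seq_len(floor(length(deIdx) / 2))]
  downIdx <- setdiff(deIdx, upIdx)
  shift <- numeric(p)
  shift[upIdx] <- stats::runif(length(upIdx), 1, 2)
  shift[downIdx] <- -stats::runif(length(downIdx), 1, 2)

  # correlated ordinal grades via a calibrated Gaussian copula
  k <- params@gradeRange[2] - params@gradeRange[1] + 1L
  rho <- .calibrateLatentRho(params@gradeCorrelation, k)
  zT <- stats::rnorm(n)
  zF <- rho * zT + sqrt(1 - rho^2) * stats::rnorm(n)
  toGrade <- function(z)
    params@gradeRange[1] +
      pmin(k - 1L, floor(stats::pnorm(z) * k))
  gT <- as.integer(toGrade(zT))
  gF <- as.integer(toGrade(zF))

  sampleIds <- c(sprintf("S%03d", seq_len(nD)),
                 if (nV > 0) sprintf("V%03d", seq_len(nV)))
  role <- c(rep("discovery", nD), rep("validation", nV))
  disease <- c(.drawDiseases(nD),
               if (nV > 0) .drawDiseases(nV)[seq_len(nV)] else character())

  markerEffect <- numeric(p)
  markerEffect[markerProbeIdx] <- 1
  expectedLog2 <- baseline + outer(shift, rep(1, n)) +
    outer(markerEffect, gT) * params@effectSlopeLog2
  log2I <- expectedLog2 + stats::rnorm(p * n, 0, params@noiseSdLog2)
  intensity <- 2^log2I
  dimnames(intensity) <- list(probeIds, sampleIds)

  control <- 2^(baseline + stats::rnorm(p, 0, params@noiseSdLog2))

  badSpot <- matrix(0L, p, n, dimnames = dimnames(intensity))
  nBad <- round(params@badSpotFraction * p * n)
  if (nBad > 0) {
    cells <- sample(p * n, nBad)
    badSpot[cells] <- 1L
    intensity[cells] <- intensity[cells] * 2^stats::runif(nBad, -3, 3)
  }

  colData <- DataFrame(disease = disease, fibrosis_grade = gF,
                       tubular_damage_grade = gT, role = role,
                       row.names = sampleIds)
  truth <- new("SyntheticTruth",
               markerProbeIds = probeIds[markerProbeIdx],
               gradeIndependentUp = probeIds[upIdx],
               gradeIndependentDown = probeIds[downIdx],
               undetectableProbeIds = probeIds[undetIdx],
               perSampleGrades = DataFrame(sample_id = sampleIds,
                                           fibrosis_grade = gF,
                                           tubular_damage_grade = gT),
               seed = params@seed)
  KidneyArrayExperiment(intensity = intensity, control = control,
                        colData = colData, gene = gene, bgMean = bgMean,
                        bgSd = bgSd, badSpot = badSpot,
                        metadata = list(truth = truth, params = params))
}
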