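suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

# Small simulated cohort for fast unit tests.
smallParams <- function(...) {
  defaults <- list(nProbes = 500L, nDiscovery = 24L, nValidation = 3L,
                   seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationParams, args)
}

# Hand-built toy experiment from explicit matrices.
toyExperiment <- function(intensity, control = NULL, grades = NULL,
                          gene = NULL, bgMean = NULL, bgSd = NULL,
                          badSpot = NULL, role = NULL) {
  p <- nrow(intensity)
  n <- ncol(intensity)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("P%02d", seq_len(p))
  if (is.null(colnames(intensity)))
    colnames(intensity) <- sprintf("S%02d", seq_len(n))
  if (is.null(control)) control <- rep(1, p)
  if (is.null(grades)) grades <- round(seq(1, 4, length.out = n))
  if (is.null(role)) role <- rep("discovery", n)
  cd <- DataFrame(disease = rep("IgA nephropathy", n),
                  fibrosis_grade = as.integer(grades),
                  tubular_damage_grade = as.integer(grades),
                  role = role, row.names = colnames(intensity))
  KidneyArrayExperiment(intensity = intensity, control = control,
                        colData = cd, gene = gene, bgMean = bgMean,
                        bgSd = bgSd, badSpot = badSpot)
}

# Fold-change profile with prescribed log2 ratios (control fixed at 1).
toyFoldChange <- function(log2mat, gene = NULL, grades = NULL,
                          role = NULL) {
  x <- toyExperiment(2^log2mat, gene = gene, grades = grades, role = role)
  computeFoldChange(x, floor = 1e-6)
}

# Standard preprocessed fold-change profile from a simulated cohort.
preprocessCohort <- function(cohort) {
  cohort <- medianNormalize(dropBadSpots(cohort))
  det <- filterDetectable(cohort)
  computeFoldChange(cohort, detectable = det$probeDetectable)
}
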