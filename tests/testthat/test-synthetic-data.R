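test_that("invalid simulation parameters are rejected with the field named", {
  expect_error(simulationParams(noiseSdLog2 = 0), "noiseSdLog2")
  expect_error(simulationParams(badSpotFraction = 1), "badSpotFraction")
  expect_error(simulationParams(gradeRange = c(4L, 1L)), "gradeRange")
  expect_error(simulationParams(gradeCorrelation = 1.2), "gradeCorrelation")
  expect_error(simulationParams(nProbes = 5, nMarkerGenes = 5,
                                probesPerMarkerGene = 2), "nMarkerGenes")
})

test_that("identical seeds give identical cohorts", {
  a <- generateCohort(smallParams())
  b <- generateCohort(smallParams())
  expect_identical(assay(a, "intensity"), assay(b, "intensity"))
  expect_identical(assay(a, "badSpot"), assay(b, "badSpot"))
  expect_identical(controlProfile(a), controlProfile(b))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
  expect_identical(cohortTruth(a)@markerProbeIds,
                   cohortTruth(b)@markerProbeIds)
  c <- generateCohort(smallParams(seed = 43L))
  expect_false(identical(assay(a, "intensity"), assay(c, "intensity")))
})

test_that("the null model plants no expected fold change anywhere", {
  co <- generateCohort(smallParams(effectSlopeLog2 = 0, nDiscovery = 60L,
                                   badSpotFraction = 0))
  tr <- cohortTruth(co)
  expect_gt(length(tr@markerProbeIds), 0)
  lr <- log2(assay(co, "intensity")[tr@markerProbeIds, ] /
               controlProfile(co)[tr@markerProbeIds])
  # mean log2 ratio of marker probes ~ 0 within Monte-Carlo error
  se <- sd(rowMeans(lr)) / sqrt(nrow(lr))
  expect_lt(abs(mean(lr)), 4 * se)
})

test_that("marker calibration: grade-4 mean log2 ratio matches slope x grade", {
  co <- generateCohort(simulationParams(seed = 1))
  tr <- cohortTruth(co)
  cd <- colData(co)
  g4 <- rownames(cd)[cd$tubular_damage_grade == 4 & cd$role == "discovery"]
  expect_gt(length(g4), 0)
  lr <- log2(assay(co, "intensity")[tr@markerProbeIds, g4] /
               controlProfile(co)[tr@markerProbeIds])
  perProbe <- rowMeans(lr)
  se <- sd(perProbe) / sqrt(length(perProbe))
  expect_lt(abs(mean(perProbe) - 0.8 * 4), 3 * se)
})

test_that("null probes are calibrated around ratio 1", {
  co <- generateCohort(smallParams(nProbes = 1200L, nDiscovery = 48L,
                                   badSpotFraction = 0))
  tr <- cohortTruth(co)
  nullProbes <- setdiff(rownames(co),
                        c(tr@markerProbeIds, tr@gradeIndependentUp,
                          tr@gradeIndependentDown, tr@undetectableProbeIds))
  nullProbes <- nullProbes[seq_len(1000)]
  lr <- log2(assay(co, "intensity")[nullProbes, ] /
               controlProfile(co)[nullProbes])
  perProbe <- rowMeans(lr)
  se <- sd(perProbe) / sqrt(length(perProbe))
  expect_lt(abs(mean(perProbe)), 4 * se)
})

test_that("the two grade vectors attain the requested rank correlation", {
  for (target in c(0.5, 0.8)) {
    co <- generateCohort(smallParams(nProbes = 20L, nDiscovery = 400L,
                                     nValidation = 0L,
                                     gradeCorrelation = target, seed = 7L))
    cd <- colData(co)
    rho <- cor(cd$fibrosis_grade, cd$tubular_damage_grade,
               method = "spearman")
    expect_lt(abs(rho - target), 0.1)
  }
})

test_that("planted truth is structured and disjoint", {
  co <- generateCohort(smallParams(nProbes = 400L,
                                   backgroundDeFraction = 0.1))
  tr <- cohortTruth(co)
  expect_length(intersect(tr@markerProbeIds, tr@gradeIndependentUp), 0)
  expect_length(intersect(tr@markerProbeIds, tr@gradeIndependentDown), 0)
  expect_length(intersect(tr@gradeIndependentUp, tr@gradeIndependentDown), 0)
  expect_true(all(tr@markerProbeIds %in% rownames(co)))
  cd <- colData(co)
  expect_true(all(cd$fibrosis_grade %in% 0:5))
  expect_true(all(cd$tubular_damage_grade %in% 0:5))
  # marker probes carry the panel gene symbols, several probes per gene
  genes <- rowData(co)[tr@markerProbeIds, "gene"]
  expect_setequal(unique(genes), markerPanel())
})

test_that("cohort write/read round-trips", {
  dir <- withr::local_tempdir()
  co <- generateCohort(smallParams(nProbes = 120L, nDiscovery = 6L,
                                   nValidation = 2L))
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_equal(assay(back, "intensity"), assay(co, "intensity"),
               tolerance = 1e-8)
  expect_equal(unname(controlProfile(back)), unname(controlProfile(co)),
               tolerance = 1e-8)
  expect_identical(as.data.frame(colData(back)), as.data.frame(colData(co)))
  expect_identical(assay(back, "badSpot") != 0, assay(co, "badSpot") != 0)
  expect_identical(cohortTruth(back)@markerProbeIds,
                   cohortTruth(co)@markerProbeIds)
  expect_identical(cohortTruth(back)@seed, cohortTruth(co)@seed)
})

test_that("cohort files are header-rowed TSVs", {
  dir <- withr::local_tempdir()
  co <- generateCohort(smallParams(nProbes = 50L, nDiscovery = 4L,
                                   nValidation = 1L))
  writeCohort(co, dir)
  for (f in c("expression.tsv", "control.tsv", "background.tsv",
              "flags.tsv", "metadata.tsv"))
    expect_true(file.exists(file.path(dir, f)), label = f)
  header <- strsplit(readLines(file.path(dir, "expression.tsv"), n = 1),
                     "\t")[[1]]
  expect_identical(header, c("probe_id", colnames(co)))
  md <- read.delim(file.path(dir, "metadata.tsv"))
  expect_identical(colnames(md),
                   c("sample_id", "disease", "fibrosis_grade",
                     "tubular_damage_grade", "role"))
})

test_that("reading an incomplete cohort directory names the missing file", {
  dir <- withr::local_tempdir()
  co <- generateCohort(smallParams(nProbes = 30L, nDiscovery = 4L))
  writeCohort(co, dir)
  file.remove(file.path(dir, "metadata.tsv"))
  expect_error(readCohort(dir), "metadata.tsv")
  expect_error(readCohort(file.path(dir, "nope")), "not found")
})
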