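test_that("the molecular score is the geometric mean of marker fold changes", {
  # all marker fold changes 1 -> score 1
  fc <- toyFoldChange(matrix(0, 4, 2), gene = c("A", "A", "B", "B"))
  sc <- molecularScore(fc, genes = c("A", "B"))
  expect_equal(unname(scoreValues(sc)), c(1, 1))
  # two probes {2, 8} -> sqrt(16) = 4
  fc2 <- toyFoldChange(matrix(log2(c(2, 8)), 2, 1), gene = c("A", "A"))
  expect_equal(unname(scoreValues(molecularScore(fc2, genes = "A"))), 4)
  # five probes {1.5, 2, 4, 0.5, 3} -> (product)^(1/5), frozen from the
  # product-root form: 18^(1/5)
  vals <- c(1.5, 2, 4, 0.5, 3)
  fc5 <- toyFoldChange(matrix(log2(vals), 5, 1),
                       gene = c("A", "A", "B", "B", "C"))
  expect_equal(unname(scoreValues(molecularScore(fc5, genes = c("A", "B", "C")))),
               18^0.2, tolerance = 1e-12)
  expect_equal(18^0.2, exp(mean(log(vals))), tolerance = 1e-15)
})

test_that("scoring records probes used and errors on uncovered genes", {
  fc <- toyFoldChange(matrix(0, 4, 1), gene = c("A", "A", "B", "B"))
  sc <- molecularScore(fc, genes = c("A", "B"))
  expect_setequal(markerProbes(sc), rownames(fc))
  expect_identical(markerGenes(sc), c("A", "B"))
  expect_error(molecularScore(fc, genes = c("A", "NKX6-2")), "NKX6-2")
})

test_that("score homogeneity: scaling fold changes scales the score by c", {
  set.seed(12)
  lr <- matrix(rnorm(20), 10, 2)
  gene <- rep(c("A", "B", "C", "D", "E"), each = 2)
  s1 <- scoreValues(molecularScore(toyFoldChange(lr, gene = gene),
                                   genes = c("A", "B")))
  s2 <- scoreValues(molecularScore(toyFoldChange(lr + log2(7), gene = gene),
                                   genes = c("A", "B")))
  expect_equal(s2, 7 * s1, tolerance = 1e-12)
})

test_that("AUC equals exhaustive pair counting with tie credit 1/2", {
  # perfect separation and complete ties
  expect_equal(aucValue(rocAuc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))), 1)
  expect_equal(aucValue(rocAuc(rep(2, 6), rep(c(TRUE, FALSE), 3))), 0.5)
  # 8-sample toy vector with ties
  s <- c(1, 2, 2, 3, 3, 3, 4, 5)
  l <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(aucValue(rocAuc(s, l)), aucPairOracle(s, l))
  # 200 random toy instances
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    s <- sample(round(runif(n, 0, 4), 1), n, replace = TRUE)
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(l) || !any(l)) l[1:2] <- c(TRUE, FALSE)
    expect_equal(aucValue(rocAuc(s, l)), aucPairOracle(s, l),
                 tolerance = 1e-12)
  }
  expect_error(rocAuc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("the ROC curve is a valid step function consistent with its AUC", {
  set.seed(14)
  s <- round(runif(20, 0, 3), 1)
  l <- rep(c(TRUE, FALSE), 10)
  roc <- rocAuc(s, l)
  expect_equal(roc@sensitivity[1], 0)
  expect_equal(roc@fpr[1], 0)
  expect_equal(roc@sensitivity[length(roc@sensitivity)], 1)
  expect_equal(roc@fpr[length(roc@fpr)], 1)
  expect_true(all(diff(roc@sensitivity) >= 0))
  expect_true(all(diff(roc@fpr) >= 0))
  # trapezoidal area under the step curve equals the rank AUC
  area <- sum(diff(roc@fpr) * (roc@sensitivity[-1] +
                                 head(roc@sensitivity, -1)) / 2)
  expect_equal(area, aucValue(roc), tolerance = 1e-12)
})

test_that("AUC matches an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (i in 1:20) {
    s <- round(rnorm(30), 1)
    l <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (all(l) || !any(l)) l[1:2] <- c(TRUE, FALSE)
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(l, s,
                                                           direction = "<"))))
    expect_equal(aucValue(rocAuc(s, l)), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(16)
  s <- runif(25, 0.1, 5)
  l <- sample(c(TRUE, FALSE), 25, replace = TRUE)
  l[1:2] <- c(TRUE, FALSE)
  a <- aucValue(rocAuc(s, l))
  expect_equal(aucValue(rocAuc(log(s), l)), a)
  expect_equal(aucValue(rocAuc(s^3, l)), a)
  expect_equal(aucValue(rocAuc(rank(s), l)), a)
})

test_that("grade-dichotomization AUCs match exhaustive pair counting", {
  scores <- c(a = 1.2, b = 0.8, c = 2.5, d = 3.1, e = 2.2, f = 4.0)
  md <- S4Vectors::DataFrame(
    fibrosis_grade = c(1L, 1L, 2L, 3L, 3L, 4L),
    tubular_damage_grade = c(1L, 2L, 2L, 3L, 4L, 4L),
    row.names = names(scores))
  tab <- gradeDichotomizationAuc(scores, md)
  expect_identical(nrow(tab), 9L)
  for (i in seq_len(nrow(tab))) {
    g <- if (tab$endpoint[i] == "fibrosis") md$fibrosis_grade
         else if (tab$endpoint[i] == "tubular") md$tubular_damage_grade
         else c(md$fibrosis_grade, md$tubular_damage_grade)
    s <- if (tab$endpoint[i] == "composite") c(scores, scores) else scores
    expect_equal(tab$auc[i], aucPairOracle(s, g > tab$cut[i]),
                 label = paste(tab$endpoint[i], tab$cut[i]))
  }
  # a single-class dichotomization is undefined, not an error
  md2 <- md
  md2$fibrosis_grade <- rep(2L, 6)
  tab2 <- gradeDichotomizationAuc(scores, md2)
  expect_true(is.na(tab2$auc[tab2$endpoint == "fibrosis" & tab2$cut == 3]))
})

test_that("threshold derivation maximizes Youden J, at a midpoint cutoff", {
  scores <- c(s1 = 1, s2 = 1.5, s3 = 2, s4 = 2.2, s5 = 3, s6 = 3.5,
              s7 = 4.2, s8 = 5, s9 = 5.5, s10 = 7)
  g <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L)
  md <- S4Vectors::DataFrame(fibrosis_grade = g, tubular_damage_grade = g,
                             row.names = names(scores))
  th <- deriveThresholds(scores, md)
  pooled <- rep(scores, 2)
  for (cutGrade in c(2L, 3L)) {
    labels <- rep(g, 2) > cutGrade
    cutoff <- if (cutGrade == 2L) thresholdI(th) else thresholdII(th)
    expect_equal(youdenJ(pooled, labels, cutoff),
                 youdenScanOracle(pooled, labels)$bestJ,
                 label = sprintf("grade cut %d", cutGrade))
  }
  # perfect separation: threshold sits strictly between the classes
  expect_gt(thresholdI(th), 3)
  expect_lt(thresholdI(th), 3.5)
  expect_equal(thresholdI(th), (3 + 3.5) / 2)
  expect_gte(thresholdII(th), thresholdI(th))
  # deterministic and idempotent
  expect_equal(deriveThresholds(scores, md)@thresholdI, thresholdI(th))
  # degenerate single-class cut errors
  expect_error(deriveThresholds(scores[1:2], md[1:2, ]), "single-class")
})

test_that("threshold derivation matches the exhaustive scan on noisy toys", {
  set.seed(17)
  for (i in 1:20) {
    n <- 12
    g <- sample(1:4, n, replace = TRUE)
    if (length(unique(g > 2)) < 2 || length(unique(g > 3)) < 2) next
    s <- setNames(round(exp(0.5 * g + rnorm(n, 0, 0.6)), 2),
                  sprintf("x%02d", 1:n))
    md <- S4Vectors::DataFrame(fibrosis_grade = g, tubular_damage_grade = g,
                               row.names = names(s))
    th <- deriveThresholds(s, md)
    pooled <- rep(s, 2)
    labels <- rep(g, 2) > 2
    expect_equal(youdenJ(pooled, labels, thresholdI(th)),
                 youdenScanOracle(pooled, labels)$bestJ)
  }
})

test_that("grade-category prediction uses strict inequalities at both thresholds", {
  th <- new("GradeThresholds", thresholdI = 2, thresholdII = 4,
            method = "youden", derivation = list())
  pred <- predictGradeCategory(c(5, 1, 2, 4, 3), th)
  expect_identical(pred$category_I, c(">=3", "<=2", "<=2", ">=3", ">=3"))
  expect_identical(pred$category_II, c(">=4", "<=3", "<=3", "<=3", "<=3"))
  # scores exactly at a threshold stay in the lower category
  expect_identical(predictGradeCategory(2, th)$category_I, "<=2")
  expect_identical(predictGradeCategory(4, th)$category_II, "<=3")
})

test_that("validation scoring flags concordance per endpoint", {
  lr <- matrix(rep(c(0.5, 3), each = 2), 2, 2)  # sample scores 2^0.5, 2^3
  rownames(lr) <- c("p1", "p2")
  colnames(lr) <- c("v1", "v2")
  x <- toyExperiment(2^lr, gene = c("A", "B"),
                     grades = c(2L, 4L), role = rep("validation", 2))
  fc <- computeFoldChange(x, floor = 1e-6, meanSamples = colnames(x))
  th <- new("GradeThresholds", thresholdI = 3, thresholdII = 6,
            method = "youden", derivation = list())
  pred <- validateCohort(fc, th, genes = c("A", "B"))
  expect_identical(pred$category_I, c("<=2", ">=3"))
  expect_identical(pred$category_II, c("<=3", ">=4"))
  expect_true(all(pred$concordant_I_tubular))
  expect_true(all(pred$concordant_II_tubular))
  # grade exactly at the cut: concordant iff predicted ">=3"
  x3 <- toyExperiment(2^lr, gene = c("A", "B"),
                      grades = c(3L, 3L), role = rep("validation", 2))
  fc3 <- computeFoldChange(x3, floor = 1e-6, meanSamples = colnames(x3))
  pred3 <- validateCohort(fc3, th, genes = c("A", "B"))
  expect_identical(pred3$concordant_I_tubular, c(FALSE, TRUE))
  # empty validation set: empty table, no error
  empty <- validateCohort(fc, th, genes = c("A", "B"), samples = character())
  expect_identical(nrow(empty), 0L)
  # probe-set mismatch is an explicit error
  expect_error(validateCohort(fc, th, genes = c("A", "B"),
                              markerProbes = c("p1", "p9")), "mismatch")
})

test_that("the score tracks the driving grade on simulated cohorts", {
  rhos <- sapply(1:5, function(s) {
    co <- generateCohort(simulationParams(nProbes = 1000L, seed = s))
    fc <- preprocessCohort(co)
    disc <- colnames(fc)[colData(fc)$role == "discovery"]
    sc <- scoreValues(molecularScore(fc, samples = disc))
    cor(sc, colData(fc)[disc, "tubular_damage_grade"], method = "spearman")
  })
  expect_gte(median(rhos), 0.7)
  # null model: correlation centred on zero
  co0 <- generateCohort(simulationParams(nProbes = 1000L,
                                         effectSlopeLog2 = 0, seed = 21L))
  fc0 <- preprocessCohort(co0)
  disc <- colnames(fc0)[colData(fc0)$role == "discovery"]
  sc0 <- scoreValues(molecularScore(fc0, samples = disc))
  rho0 <- cor(sc0, colData(fc0)[disc, "tubular_damage_grade"],
              method = "spearman")
  expect_lt(abs(rho0), 0.5)
})

test_that("discovery-fitted thresholds classify held-out validation samples", {
  hits <- sapply(1:50, function(s) {
    co <- generateCohort(simulationParams(nProbes = 2000L, seed = s))
    fc <- preprocessCohort(co)
    disc <- colnames(fc)[colData(fc)$role == "discovery"]
    scD <- scoreValues(molecularScore(fc, samples = disc))
    th <- deriveThresholds(scD, colData(fc))
    pred <- validateCohort(fc, th)
    c(tub = mean(pred$concordant_I_tubular) == 1,
      ord = thresholdII(th) >= thresholdI(th))
  })
  expect_gte(mean(hits["tub", ]), 0.9)
  expect_true(all(hits["ord", ]))
})
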