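# Independent oracles, kept free of the package's own code paths.

# Kruskal-Wallis H by the explicit midrank formula with tie correction,
# P from the chi-square approximation.
kwFormulaOracle <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, groups, mean)
  ni <- tabulate(groups)
  H <- 12 / (n * (n + 1)) * sum(ni * (Rbar - (n + 1) / 2)^2)
  tie <- table(values)
  C <- 1 - sum(tie^3 - tie) / (n^3 - n)
  if (C == 0) return(list(H = 0, P = 1))
  H <- H / C
  list(H = unname(H),
       P = stats::pchisq(H, nlevels(groups) - 1L, lower.tail = FALSE))
}

# Exact permutation distribution of H over all assignments of the observed
# values to the observed group sizes (small n only).
kwPermutationDistribution <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  perms <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], Recall(v[-i])))
    out
  }
  labelings <- unique(perms(as.integer(groups)))
  apply(labelings, 1, function(g) kwFormulaOracle(values, g)$H)
}

# Exhaustive positive-negative pair counting AUC with tie credit 1/2.
aucPairOracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Best achievable Youden J over every cutoff (grid of all observed scores
# plus points between and beyond), prediction positive when score > cutoff.
youdenScanOracle <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  grid <- sort(c(u, u - 1e-9, u[1] - 1, u[length(u)] + 1,
                 (u[-1] + u[-length(u)]) / 2))
  J <- vapply(grid, function(t)
    mean(scores[labels] > t) + mean(scores[!labels] <= t) - 1, 0)
  list(bestJ = max(J), cutoffs = grid)
}

youdenJ <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  mean(scores[labels] > cutoff) + mean(scores[!labels] <= cutoff) - 1
}

# All ways to split n indices into k labelled nonempty groups.
allGroupLabelings <- function(n, k) {
  grids <- do.call(expand.grid, rep(list(seq_len(k)), n))
  keep <- apply(grids, 1, function(g) length(unique(g)) == k)
  as.matrix(grids[keep, , drop = FALSE])
}
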