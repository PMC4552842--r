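#' Restrict to discovery samples of given disease categories
#'
#' Returns, in their original order, the discovery-set samples whose primary
#' disease falls in \code{categories}. The conventional subset for grade
#' association is \code{\link{glomerulopathyCategories}} (primary
#' glomerulonephritis plus diabetic nephropathy).
#'
#' @param x a \linkS4class{KidneyArrayExperiment},
#'   \linkS4class{FoldChangeProfile}, or a data.frame/DataFrame of sample
#'   metadata with \code{disease} and \code{role} columns.
#' @param categories nonempty character vector of disease categories.
#' @return Character vector of sample ids.
#' @export
subsetByDisease <- function(x, categories = glomerulopathyCategories()) {
  if (!length(categories))
    stop("categories must be nonempty")
  cd <- if (is(x, "SummarizedExperiment")) colData(x) else x
  if (!all(c("disease", "role") %in% colnames(cd)))
    stop("sample metadata must contain 'disease' and 'role'")
  ids <- rownames(cd)[cd$role == "discovery" & cd$disease %in% categories]
  if (!length(ids))
    stop("no discovery samples in the requested disease categories")
  ids
}

#' Kruskal-Wallis rank test
#'
#' Midrank-based k-sample test with the standard tie correction, with the P
#' value from the chi-square approximation on (k - 1) degrees of freedom
#' (via \code{stats::kruskal.test}). The degenerate all-tied input, where
#' the tie correction is 0/0, is defined as H = 0, P = 1 (no rank
#' variation).
#'
#' @param values numeric observations.
#' @param groups group labels (here: ordinal histopathology grades).
#' @return A list with elements \code{H} and \code{P}.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("groups: need at least 2 distinct groups")
  if (length(values) != length(groups) || length(values) < 3L)
    stop("values and groups must have equal length >= 3")
  if (length(unique(values)) == 1L)
    return(list(H = 0, P = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), P = unname(kt$p.value))
}

#' Dual-endpoint grade association
#'
#' Tests each candidate probe's per-sample fold change against the fibrosis
#' grade and, separately, the tubular-damage grade with the Kruskal-Wallis
#' test over the given samples. Each observed grade value forms its own
#' group (no binning). A probe is \code{selected} when both P values fall
#' below \code{alpha}. No multiple-testing correction is applied by default
#' (raw P < alpha); Benjamini-Hochberg adjustment per endpoint is available
#' via \code{adjust}.
#'
#' @param fc a \linkS4class{FoldChangeProfile}.
#' @param candidates probe ids to test (typically the up-regulated set).
#' @param samples sample ids to test over (typically from
#'   \code{\link{subsetByDisease}}).
#' @param alpha significance level (default 0.05).
#' @param adjust apply Benjamini-Hochberg adjustment per endpoint before
#'   thresholding (default FALSE).
#' @return An \linkS4class{AssociationResult}.
#' @export
dualEndpointSelection <- function(fc, candidates, samples, alpha = 0.05,
                                  adjust = FALSE) {
  stopifnot(is(fc, "FoldChangeProfile"))
  if (!all(candidates %in% rownames(fc)))
    stop("candidates must be probes present in the fold-change profile")
  if (!all(samples %in% colnames(fc)))
    stop("samples must be present in the fold-change profile")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha: must be in [0, 1]")
  cd <- colData(fc)[samples, , drop = FALSE]
  gF <- cd$fibrosis_grade
  gT <- cd$tubular_damage_grade
  for (g in list(fibrosis = gF, tubular = gT))
    if (length(unique(g)) < 2L)
      stop("fewer than 2 distinct grades in the sample subset; ",
           "grade association is undefined")
  ratios <- assay(fc, "foldChange")[candidates, samples, drop = FALSE]
  testEndpoint <- function(grades) {
    res <- apply(ratios, 1, function(v) unlist(kruskalWallis(v, grades)))
    list(H = res["H", ], P = res["P", ])
  }
  fib <- testEndpoint(gF)
  tub <- testEndpoint(gT)
  pF <- if (adjust) stats::p.adjust(fib$P, "BH") else fib$P
  pT <- if (adjust) stats::p.adjust(tub$P, "BH") else tub$P
  gene <- if ("gene" %in% colnames(rowData(fc)))
    rowData(fc)[candidates, "gene"] else candidates
  tab <- DataFrame(probe_id = candidates, gene = gene,
                   H_fibrosis = unname(fib$H), P_fibrosis = unname(pF),
                   H_tubular = unname(tub$H), P_tubular = unname(pT),
                   selected = unname(pF < alpha & pT < alpha),
                   row.names = candidates)
  new("AssociationResult", table = tab, alpha = alpha,
      samples = as.character(samples), adjusted = isTRUE(adjust))
}

#' Genes significant per endpoint and for both
#'
#' @param assoc an \linkS4class{AssociationResult}.
#' @return A list with character vectors \code{fibrosis}, \code{tubular}
#'   (genes with any probe significant for that endpoint) and \code{both}
#'   (genes with any probe significant for both endpoints).
#' @export
significantGenes <- function(assoc) {
  stopifnot(is(assoc, "AssociationResult"))
  tab <- assoc@table
  a <- assoc@alpha
  list(fibrosis = unique(tab$gene[tab$P_fibrosis < a]),
       tubular = unique(tab$gene[tab$P_tubular < a]),
       both = unique(tab$gene[tab$selected]))
}
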