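#' z-score standardization of cohort-mean fold changes
#'
#' Standardizes each detectable probe's cohort-mean ratio across probes: on
#' the default \code{"log2"} scale, \code{z = (log2(meanRatio) - m) / s}
#' where \code{m} and \code{s} are the across-probe mean and sample
#' (n - 1) standard deviation. One z per probe; probes with \code{|z|}
#' beyond the cutoff are labelled \code{up} / \code{down}.
#'
#' @param fc a \linkS4class{FoldChangeProfile}.
#' @param scale \code{"log2"} (default; ratios are strongly right-skewed,
#'   so standardization on the symmetric log scale) or \code{"linear"}.
#' @param cutoff |z| cutoff for the direction labels (default 2).
#' @return A \linkS4class{DEGResult}.
#' @export
zscoreFoldChanges <- function(fc, scale = c("log2", "linear"), cutoff = 2) {
  stopifnot(is(fc, "FoldChangeProfile"))
  scale <- match.arg(scale)
  rd <- rowData(fc)
  keep <- which(rd$detectable)
  if (length(keep) < 3L)
    stop("need at least 3 detectable probes to standardize")
  meanRatio <- rd$meanRatio[keep]
  val <- if (scale == "log2") log2(meanRatio) else meanRatio
  s <- stats::sd(val)
  if (s == 0)
    stop("zero variance across probes; z-scores are undefined")
  z <- (val - mean(val)) / s
  direction <- rep("unchanged", length(z))
  direction[z > cutoff] <- "up"
  direction[z < -cutoff] <- "down"
  gene <- if ("gene" %in% colnames(rd)) rd$gene[keep]
          else rownames(fc)[keep]
  tab <- DataFrame(probe_id = rownames(fc)[keep], gene = gene,
                   mean_ratio = unname(meanRatio),
                   log2_ratio = unname(log2(meanRatio)),
                   z = unname(z), direction = direction)
  new("DEGResult", table = tab, cutoff = cutoff, scale = scale)
}

#' Select up- and down-regulated probes
#'
#' Partitions the standardized probes by the z cutoff: \code{up} for
#' \code{z > cutoff}, \code{down} for \code{z < -cutoff}. Lists are sorted
#' by decreasing |z|.
#'
#' @param result a \linkS4class{DEGResult}.
#' @param cutoff |z| cutoff; defaults to the cutoff carried by
#'   \code{result}.
#' @return A list with character vectors \code{up} and \code{down} of probe
#'   ids.
#' @export
selectDEG <- function(result, cutoff = NULL) {
  stopifnot(is(result, "DEGResult"))
  if (is.null(cutoff)) cutoff <- result@cutoff
  tab <- result@table
  up <- tab[tab$z > cutoff, , drop = FALSE]
  down <- tab[tab$z < -cutoff, , drop = FALSE]
  list(up = up$probe_id[order(-abs(up$z))],
       down = down$probe_id[order(-abs(down$z))])
}

#' Collapse probe-level z-scores to gene level
#'
#' A gene's z is that of its maximum-|z| probe; genes are the reporting
#' unit while probes remain the measurement unit.
#'
#' @param result a \linkS4class{DEGResult}.
#' @return A \code{DataFrame} with one row per gene (\code{gene},
#'   \code{probe_id} of the representative probe, \code{z},
#'   \code{direction}).
#' @export
collapseToGenes <- function(result) {
  stopifnot(is(result, "DEGResult"))
  tab <- result@table
  ord <- order(tab$gene, -abs(tab$z))
  tab <- tab[ord, , drop = FALSE]
  tab[!duplicated(tab$gene), c("gene", "probe_id", "z", "direction")]
}
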