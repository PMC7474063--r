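#' Natural-log fold change between two cell groups
#'
#' Computes, per gene, `lnFC = ln(mean_A(expm1(x)) + 1) -
#' ln(mean_B(expm1(x)) + 1)` on the normalised log values `x`, i.e. the
#' expm1-mean convention with pseudocount 1 under which a |lnFC| of 0.1 is
#' about a 10.5% fold change and 0.7 about twofold.
#'
#' @param sce a SingleCellExperiment with a `logcounts` assay.
#' @param cellsA,cellsB non-empty cell identifiers or indices of the two
#'   groups (A over B).
#' @return named numeric vector of per-gene lnFC.
#' @export
lnFoldChange <- function(sce, cellsA, cellsB) {
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  if (length(cellsA) == 0 || length(cellsB) == 0)
    stop("both cell groups must be non-empty")
  mA <- Matrix::rowMeans(expm1(lc[, cellsA, drop = FALSE]))
  mB <- Matrix::rowMeans(expm1(lc[, cellsB, drop = FALSE]))
  log(mA + 1) - log(mB + 1)
}

## Group-wise sufficient statistics of the positive part of a logcounts
## matrix: detection counts, sums and sums of squares per gene.
.hurdleStats <- function(lc, cells) {
  x <- lc[, cells, drop = FALSE]
  list(n = length(cells),
       det = Matrix::rowSums(x > 0),
       sum = Matrix::rowSums(x),
       ssq = Matrix::rowSums(x^2))
}

## Binomial log-likelihood of k successes in n at the MLE rate, with the
## 0 log 0 = 0 convention.
.binLL <- function(k, n) {
  p <- k / n
  ifelse(k > 0, k * log(p), 0) + ifelse(n - k > 0, (n - k) * log(1 - p), 0)
}

#' Two-part (hurdle) differential-expression test
#'
#' Per gene, combines a discrete part (detection rate modelled per group,
#' binomial likelihood-ratio test) and a continuous part (Gaussian model of
#' the positive log values, likelihood-ratio test of the group mean). The
#' two statistics are summed and referred to a chi-square with one degree
#' of freedom per non-degenerate part: the discrete part is dropped when
#' detection is all-or-none in the pooled data, and the continuous part
#' when fewer than three positive cells exist in total or either group has
#' none. A gene undetected in both groups gets p = 1.
#'
#' @param sce a SingleCellExperiment with a `logcounts` assay.
#' @param cellsA,cellsB cell identifiers or indices; at least 3 cells per
#'   group.
#' @return data.frame with per-gene `stat`, `df`, `p_raw`, and the
#'   detection fractions `pct_A`, `pct_B`.
#' @export
hurdleTest <- function(sce, cellsA, cellsB) {
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  if (length(cellsA) < 3 || length(cellsB) < 3)
    stop("need at least 3 cells per group")
  A <- .hurdleStats(lc, cellsA)
  B <- .hurdleStats(lc, cellsB)

  ## discrete part: binomial LRT on detection
  kA <- A$det; kB <- B$det; nA <- A$n; nB <- B$n
  l1 <- .binLL(kA, nA) + .binLL(kB, nB)
  l0 <- .binLL(kA + kB, nA + nB)
  statD <- pmax(2 * (l1 - l0), 0)
  pooled <- kA + kB
  dfD <- as.integer(pooled > 0 & pooled < nA + nB)
  statD[dfD == 0] <- 0

  ## continuous part: Gaussian LRT on positive values
  npos <- kA + kB
  rss1 <- pmax(A$ssq - ifelse(kA > 0, A$sum^2 / kA, 0), 0) +
    pmax(B$ssq - ifelse(kB > 0, B$sum^2 / kB, 0), 0)
  rss0 <- pmax(A$ssq + B$ssq - ifelse(npos > 0, (A$sum + B$sum)^2 / npos, 0), 0)
  dfC <- as.integer(npos >= 3 & kA > 0 & kB > 0)
  tiny <- 1e-300
  statC <- ifelse(dfC == 1,
                  npos * (log(pmax(rss0, tiny)) - log(pmax(rss1, tiny))),
                  0)
  statC <- pmax(statC, 0)

  stat <- statD + statC
  df <- dfD + dfC
  p <- ifelse(df > 0, pchisq(stat, df = df, lower.tail = FALSE), 1)
  data.frame(gene = rownames(lc), stat = stat, df = df, p_raw = p,
             pct_A = kA / nA, pct_B = kB / nB,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, order-preserving with the input. NA or NaN
#' inputs are an error.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, elementwise >= the raw ones.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p)) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Flag significant differential expression
#'
#' A gene is significant when its BH-adjusted p-value is strictly below
#' `alpha` AND its |lnFC| strictly exceeds `lnfcMin`. Boundary values
#' (p_adj exactly `alpha`, |lnFC| exactly `lnfcMin`) are not significant.
#'
#' @param de data.frame with columns `p_adj` and `lnFC`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lnfcMin magnitude threshold on lnFC (default 0.1).
#' @return `de` with a logical `significant` column added or replaced.
#' @export
callSignificant <- function(de, alpha = 0.05, lnfcMin = 0.1) {
  stopifnot(all(c("p_adj", "lnFC") %in% names(de)))
  de$significant <- de$p_adj < alpha & abs(de$lnFC) > lnfcMin
  de
}

#' Hurdle differential expression for one contrast
#'
#' Runs [lnFoldChange()] and [hurdleTest()] for group A versus group B,
#' BH-adjusts across all tested genes, and applies the significance rule.
#'
#' @inheritParams hurdleTest
#' @param alpha,lnfcMin thresholds passed to [callSignificant()].
#' @return data.frame with columns gene, lnFC, p_raw, p_adj, pct_A, pct_B,
#'   significant.
#' @examples
#' sim <- simulateCounts(simConfig(nCellsPerCondition = 150, nGenes = 400,
#'                                 nMarkersPerSubtype = 8,
#'                                 nAgingDEGsPerSubtype = 20,
#'                                 nSharedDEGs = 5, seed = 1))
#' sce <- normalizeLog(sim$sce)
#' aged <- colnames(sce)[sce$condition == "aged" & sce$trueLabel == "capEC"]
#' young <- colnames(sce)[sce$condition == "young" & sce$trueLabel == "capEC"]
#' de <- hurdleDE(sce, aged, young)
#' head(de[order(de$p_adj), ])
#' @export
hurdleDE <- function(sce, cellsA, cellsB, alpha = 0.05, lnfcMin = 0.1) {
  ht <- hurdleTest(sce, cellsA, cellsB)
  lfc <- lnFoldChange(sce, cellsA, cellsB)
  zero <- ht$pct_A == 0 & ht$pct_B == 0
  lfc[zero] <- 0
  de <- data.frame(gene = ht$gene, lnFC = unname(lfc), p_raw = ht$p_raw,
                   p_adj = bhAdjust(ht$p_raw),
                   pct_A = ht$pct_A, pct_B = ht$pct_B,
                   stringsAsFactors = FALSE)
  callSignificant(de, alpha = alpha, lnfcMin = lnfcMin)
}

#' Classify DEGs as shared or subtype-specific
#'
#' Given per-subtype DE tables over a common gene universe, reports for
#' every gene the set of subtypes where it is significant, a category
#' (shared across >= 3 subtypes, shared by 2, specific to 1, or none) and
#' whether the direction of change agrees across the significant subtypes.
#'
#' @param deList named list (subtype -> DE data.frame from [hurdleDE()]);
#'   at least two tables sharing the same gene universe.
#' @return data.frame with columns gene, nSubtypes, subtypes
#'   (comma-separated), category and concordant.
#' @export
classifySharedSpecific <- function(deList) {
  if (length(deList) < 2) stop("need at least two subtype DE tables")
  genes <- deList[[1]]$gene
  for (de in deList)
    if (!identical(sort(de$gene), sort(genes)))
      stop("all DE tables must share the same gene universe")
  sig <- sapply(deList, function(de)
    de$significant[match(genes, de$gene)])
  dir <- sapply(deList, function(de)
    sign(de$lnFC[match(genes, de$gene)]))
  nSub <- rowSums(sig)
  category <- ifelse(nSub >= 3, "shared>=3",
                     ifelse(nSub == 2, "shared(2)",
                            ifelse(nSub == 1, "specific(1)", "none")))
  subtypes <- apply(sig, 1, function(s)
    paste(names(deList)[s], collapse = ","))
  concordant <- vapply(seq_along(genes), function(i) {
    d <- dir[i, sig[i, ]]
    length(d) <= 1 || all(d == d[1])
  }, logical(1))
  data.frame(gene = genes, nSubtypes = nSub, subtypes = subtypes,
             category = category, concordant = concordant,
             stringsAsFactors = FALSE)
}
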