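#' Remove genes detected in too few cells
#'
#' Retains genes with a nonzero count in at least `minCells` cells (a gene
#' detected in exactly `minCells` cells is kept).
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param minCells minimum number of detecting cells; 0 is the identity.
#' @return the filtered SingleCellExperiment.
#' @export
filterGenesMinCells <- function(sce, minCells = 3) {
  stopifnot(minCells >= 0)
  det <- Matrix::rowSums(SummarizedExperiment::assay(sce, "counts") > 0)
  sce[det >= minCells, ]
}

#' Percentile and mitochondrial-fraction cell filtering
#'
#' Removes cells (1) strictly below the `pctLow` or strictly above the
#' `pctHigh` percentile of either total UMI count or detected-gene count,
#' or (2) with a mitochondrial count fraction strictly above `mitoMax`.
#' Percentiles are linear-interpolation quantiles computed on the input
#' population before any removal, so cells exactly at a cut point are
#' retained and an all-equal metric removes nobody.
#'
#' @param sce a SingleCellExperiment with a `counts` assay and logical
#'   `mito` column in `rowData`.
#' @param pctLow,pctHigh percentile bounds as fractions (defaults 0.05 and
#'   0.95).
#' @param mitoMax maximum tolerated mitochondrial fraction (default 0.20).
#' @return list with `sce` (filtered) and `report` (a [QCReport-class]).
#' @export
qcFilterCells <- function(sce, pctLow = 0.05, pctHigh = 0.95,
                          mitoMax = 0.20) {
  if (ncol(sce) == 0) stop("empty matrix: no cells to filter")
  m <- SummarizedExperiment::assay(sce, "counts")
  mito <- SummarizedExperiment::rowData(sce)$mito
  if (is.null(mito)) stop("rowData(sce)$mito is required")
  umi <- Matrix::colSums(m)
  ngene <- Matrix::colSums(m > 0)
  mitoFrac <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE]) /
                pmax(umi, 1) else rep(0, ncol(m))
  qUmi <- quantile(umi, c(pctLow, pctHigh), type = 7)
  qGene <- quantile(ngene, c(pctLow, pctHigh), type = 7)
  byDepth <- umi < qUmi[1] | umi > qUmi[2] |
    ngene < qGene[1] | ngene > qGene[2]
  byMito <- mitoFrac > mitoMax
  drop <- byDepth | byMito
  report <- new("QCReport",
                nCellsIn = ncol(sce), nCellsOut = as.integer(sum(!drop)),
                nGenesIn = nrow(sce), nGenesOut = nrow(sce),
                ruleCounts = c(depth_percentile = as.integer(sum(byDepth)),
                               mito_fraction = as.integer(sum(byMito))))
  list(sce = sce[, !drop], report = report)
}

#' Library-size log-normalisation
#'
#' Adds a `logcounts` assay with entries
#' `ln(1 + scale * count / cell_total)`; a zero count maps to exactly zero.
#'
#' @param sce a SingleCellExperiment with a `counts` assay; every cell must
#'   have a nonzero total (run [qcFilterCells()] first).
#' @param scale scale factor (default 1e4).
#' @return the SingleCellExperiment with a `logcounts` assay added.
#' @export
normalizeLog <- function(sce, scale = 1e4) {
  m <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) stop("cells with zero total counts; filter them first")
  ## operate on the sparse slots so zeros stay exact zeros
  lc <- methods::as(m, "CsparseMatrix")
  perCol <- rep.int(scale / tot, diff(lc@p))
  lc@x <- log1p(lc@x * perCol)
  SummarizedExperiment::assay(sce, "logcounts") <- lc
  sce
}

#' Select high-variance genes
#'
#' Ranks genes by standardised variance: the variance of the normalised
#' values divided by a degree-2 polynomial mean-variance trend fitted across
#' genes on the log-variance scale (so the trend stays positive). The trend
#' is fitted twice, the second pass leaving out the top decile of
#' first-pass standardised variances so that genuinely variable genes do
#' not drag the trend toward themselves. Ordering is deterministic, ties
#' broken by gene identifier.
#'
#' @param sce a SingleCellExperiment with a `logcounts` assay.
#' @param n number of genes to return (must not exceed the gene count).
#' @return character vector of `n` gene identifiers, highest standardised
#'   variance first.
#' @export
selectHVG <- function(sce, n = 4000) {
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  if (n > nrow(lc)) stop("n exceeds the number of genes")
  mu <- Matrix::rowMeans(lc)
  v <- Matrix::rowSums(lc^2) / ncol(lc) - mu^2
  v <- v * ncol(lc) / max(ncol(lc) - 1L, 1L)
  ## degree-2 trend on the log-variance scale: strictly positive fitted
  ## values, and variance outliers exert far less leverage
  trend <- function(keep) {
    keep <- keep & v > 0
    fit <- lm(log(v) ~ mu + I(mu^2), subset = keep)
    exp(as.numeric(cbind(1, mu, mu^2) %*% coef(fit)))
  }
  std <- v / trend(rep(TRUE, length(v)))
  std <- v / trend(std <= quantile(std, 0.9))
  std[v == 0] <- 0   # constant genes can never be selected
  ord <- order(-std, rownames(lc))
  rownames(lc)[ord][seq_len(n)]
}

#' Marker-score assignment of primary cell types
#'
#' Scores each cell for each primary type as the mean normalised expression
#' of the type's marker genes, labels cells by the argmax score, and
#' excludes cells whose top two scores are both high (dual-high expression
#' of two or more cell-type marker programs, the signature of doublets or
#' contaminated transcriptomes). "High" for a type means the score exceeds
#' the type's baseline (median score of cells not labelled as it) by more
#' than `dualHighFactor` of the gap to its positive level (90th-percentile
#' score of the cells labelled as it), so the bar tracks genuinely positive
#' cells even for rare populations and for markers with a high baseline.
#'
#' @param sce a SingleCellExperiment with a `logcounts` assay.
#' @param markerTable named list: primary type -> character vector of
#'   marker genes. A marker absent from the matrix is skipped with a
#'   warning; a type with no marker present is an error.
#' @param dualHighFactor multiplier of the per-type 90th-percentile score
#'   used as the dual-high bar (default 0.5).
#' @return list with `label` (factor per cell, NA for excluded cells),
#'   `excluded` (logical per cell) and `scores` (cells x types matrix).
#' @export
assignPrimaryCellTypes <- function(sce, markerTable, dualHighFactor = 0.5) {
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  scores <- sapply(names(markerTable), function(ct) {
    g <- markerTable[[ct]]
    missing <- setdiff(g, rownames(lc))
    if (length(missing))
      warning("markers absent from matrix for ", ct, ": ",
              paste(missing, collapse = ", "))
    g <- intersect(g, rownames(lc))
    if (length(g) == 0) stop("no marker of type ", ct, " present in matrix")
    Matrix::colMeans(lc[g, , drop = FALSE])
  })
  lab <- colnames(scores)[max.col(scores, ties.method = "first")]
  bar <- vapply(colnames(scores), function(ct) {
    own <- scores[lab == ct, ct]
    if (length(own) == 0) own <- scores[, ct]
    others <- scores[lab != ct, ct]
    if (length(others) == 0) others <- scores[, ct]
    base <- median(others)
    base + dualHighFactor * (quantile(own, probs = 0.9, type = 7) - base)
  }, numeric(1))
  top2 <- t(apply(scores, 1, function(s) order(s, decreasing = TRUE)[1:2]))
  excluded <- scores[cbind(seq_len(nrow(scores)), top2[, 1])] > bar[top2[, 1]] &
    scores[cbind(seq_len(nrow(scores)), top2[, 2])] > bar[top2[, 2]]
  label <- factor(ifelse(excluded, NA, lab), levels = names(markerTable))
  names(label) <- colnames(sce)
  names(excluded) <- colnames(sce)
  list(label = label, excluded = excluded, scores = scores)
}
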