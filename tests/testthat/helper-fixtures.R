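## Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

## A small balanced simulation used by several files: 6 subtypes x ~90
## cells/condition, modest marker panel, planted aging effects.
smallSim <- function() {
  if (is.null(.fixtures$smallSim)) {
    cfg <- simConfig(nCellsPerCondition = 90,
                     subtypeProportions = setNames(rep(1 / 6, 6),
                                                   zonationSubtypes()),
                     nGenes = 800, nMarkersPerSubtype = 8,
                     nECEnrichedGenes = 12, nAgingDEGsPerSubtype = 20,
                     nSharedDEGs = 6, seed = 101)
    .fixtures$smallSim <- simulateCounts(cfg)
  }
  .fixtures$smallSim
}

## Build a SingleCellExperiment straight from a dense count matrix.
sceFromCounts <- function(counts, mito = NULL, logcounts = FALSE) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  if (is.null(mito)) mito <- rep(FALSE, nrow(counts))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    rowData = S4Vectors::DataFrame(mito = mito, row.names = rownames(counts)))
  if (logcounts) sce <- normalizeLog(sce)
  sce
}

## SCE with a prescribed logcounts matrix (for closed-form lnFC checks).
sceFromLogcounts <- function(lc) {
  if (is.null(rownames(lc)))
    rownames(lc) <- sprintf("g%03d", seq_len(nrow(lc)))
  if (is.null(colnames(lc)))
    colnames(lc) <- sprintf("c%03d", seq_len(ncol(lc)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(lc, sparse = TRUE),
                  logcounts = Matrix::Matrix(lc, sparse = TRUE)))
}

## Hand step-up BH oracle, independent of stats::p.adjust.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  val <- p[o] * m / seq_len(m)
  val <- rev(cummin(rev(val)))
  val <- pmin(val, 1)
  out <- numeric(m)
  out[o] <- val
  out
}

## Exhaustive hypergeometric upper-tail oracle: enumerate all size-n draws
## from a universe of N elements of which the first K are "disease".
hyperEnumOracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}
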