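test_that("gene filter honours the detection boundary", {
  ## gene detected in exactly 3 cells is retained; 2 cells removed
  m <- matrix(0, 3, 10)
  m[1, 1:3] <- 1          # detected in exactly 3 cells
  m[2, 1:2] <- 7          # detected in 2 cells
  m[3, ] <- 1             # everywhere
  sce <- sceFromCounts(m)
  kept <- rownames(filterGenesMinCells(sce, 3))
  expect_true("g001" %in% kept)
  expect_false("g002" %in% kept)
  ## minCells = 0 is the identity
  expect_identical(rownames(filterGenesMinCells(sce, 0)), rownames(sce))
  ## idempotence
  once <- filterGenesMinCells(sce, 3)
  expect_identical(rownames(filterGenesMinCells(once, 3)), rownames(once))
})

test_that("cell filter matches a sort-and-slice percentile oracle", {
  ## 100 cells with strictly increasing depth and gene count: with
  ## interpolated percentiles the 5 shallowest and 5 deepest must go
  set.seed(4)
  n <- 100
  m <- matrix(0, 60, n)
  for (j in seq_len(n)) m[seq_len(10 + j %/% 3), j] <- 3 + j
  sce <- sceFromCounts(m)
  res <- qcFilterCells(sce)
  umi <- Matrix::colSums(SummarizedExperiment::assay(sce, "counts"))
  keepOracle <- rank(umi) > 5 & rank(umi) <= n - 5
  expect_identical(colnames(res$sce), colnames(sce)[keepOracle])
  expect_equal(res$report@nCellsOut, sum(keepOracle))
})

test_that("high mitochondrial fraction removes a cell regardless of depth", {
  m <- matrix(5, 10, 50)
  m[1, 25] <- round(sum(m[, 25]) / 3)   # pushes cell 25 past 25% mito
  sce <- sceFromCounts(m, mito = c(TRUE, rep(FALSE, 9)))
  mitoFrac <- m[1, 25] / sum(m[, 25])
  expect_gt(mitoFrac, 0.20)
  res <- qcFilterCells(sce)
  expect_false("c025" %in% colnames(res$sce))
  expect_equal(res$report@ruleCounts[["mito_fraction"]], 1L)
})

test_that("degenerate all-equal metrics remove no cell", {
  m <- matrix(4, 8, 30)
  sce <- sceFromCounts(m)
  res <- qcFilterCells(sce)
  expect_equal(ncol(res$sce), 30)
  expect_error(qcFilterCells(sce[, 0]), "empty")
})

test_that("filters are monotone in their thresholds", {
  sim <- smallSim()
  sce <- sim$sce
  kept <- vapply(c(0.05, 0.1, 0.2, 0.5),
                 function(mm) ncol(qcFilterCells(sce, mitoMax = mm)$sce),
                 numeric(1))
  expect_true(all(diff(kept) >= 0))
  genes <- vapply(c(0, 2, 5, 20),
                  function(mc) nrow(filterGenesMinCells(sce, mc)),
                  numeric(1))
  expect_true(all(diff(genes) <= 0))
})

test_that("log-normalisation has its closed forms", {
  m <- matrix(c(5, 0, 3, 1), 2, 2)
  sce <- normalizeLog(sceFromCounts(m))
  lc <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  expect_identical(lc[2, 1], 0)                       # zero stays zero
  expect_equal(lc[1, 1], log(1 + 1e4 * 5 / 5))        # full-total count
  expect_equal(lc[1, 2], log(1 + 1e4 * 3 / 4))        # hand arithmetic
  expect_equal(lc[2, 2], log(1 + 1e4 * 1 / 4))
  m0 <- matrix(c(1, 0), 1, 2)
  expect_error(normalizeLog(sceFromCounts(m0)), "zero total")
})

test_that("high-variance gene selection ranks a spike-in first", {
  set.seed(8)
  n <- 200
  lam <- seq(0.5, 10, length.out = 50)          # a mean-variance continuum
  m <- t(vapply(lam, function(l) rpois(n, l), numeric(n)))
  m[7, ] <- 5                                   # constant gene
  m[13, ] <- rep(c(0L, 10L), n / 2)   # mid-range mean, huge variance
  sce <- normalizeLog(sceFromCounts(m))
  hv <- selectHVG(sce, 10)
  expect_identical(hv[1], "g013")
  expect_false("g007" %in% selectHVG(sce, 49))
  expect_setequal(selectHVG(sce, 50), rownames(sce))
  expect_error(selectHVG(sce, 51), "exceeds")
  ## oracle: the spike-in has the largest raw variance by a wide margin
  lc <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  expect_identical(which.max(apply(lc, 1, var)), c(g013 = 13L))
})

test_that("marker scores type cells correctly and exclude dual-high cells", {
  sim <- smallSim()
  sce <- normalizeLog(sim$sce)
  sets <- markerSets(sim$truth)
  typing <- assignPrimaryCellTypes(sce, sets[c("EC", "SMC", "PC", "MG", "AC")])
  lab <- sim$sce$trueLabel
  isDoublet <- grepl("^doublet:", lab)
  truthPrimary <- ifelse(lab %in% zonationSubtypes(), "EC", lab)
  ok <- !typing$excluded & !isDoublet
  acc <- mean(as.character(typing$label[ok]) == truthPrimary[ok])
  expect_gte(acc, 0.98)
  ## cross-primary-type doublets (the EC+PC kind) are mostly excluded
  parents <- strsplit(sub("^doublet:", "", lab[isDoublet]), "+", fixed = TRUE)
  cross <- vapply(parents, function(p)
    length(unique(ifelse(p %in% zonationSubtypes(), "EC", p))) > 1,
    logical(1))
  if (sum(cross) >= 3)
    expect_gte(mean(typing$excluded[isDoublet][cross]), 0.6)
  ## absent markers: warning when some missing, error when all missing
  sets2 <- sets[c("EC", "SMC")]
  sets2$EC <- c(sets2$EC, "not_a_gene")
  expect_warning(assignPrimaryCellTypes(sce, sets2), "absent")
  expect_error(
    suppressWarnings(
      assignPrimaryCellTypes(sce, list(EC = sets$EC, XX = "nope"))),
    "no marker")
})
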