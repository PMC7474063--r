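test_that("lnFC has its closed forms", {
  ## identical groups: exactly zero
  lc <- matrix(rep(c(0.3, 1.2, 0), 4), 3, 4)
  sce <- sceFromLogcounts(lc)
  expect_equal(unname(lnFoldChange(sce, 1:2, 3:4)), c(0, 0, 0))
  ## mean expm1 of 1 vs 0 gives ln 2
  lc2 <- matrix(0, 1, 4)
  lc2[1, 1:2] <- log(2)          # expm1 = 1
  sce2 <- sceFromLogcounts(lc2)
  expect_equal(unname(lnFoldChange(sce2, 1:2, 3:4)), log(2))
  ## toy 4-cell groups against hand arithmetic
  lc3 <- rbind(log1p(c(0, 1, 2, 3, 1, 1, 0, 0)))
  sce3 <- sceFromLogcounts(lc3)
  expect_equal(unname(lnFoldChange(sce3, 1:4, 5:8)),
               log(2.5) - log(1.5))
  expect_error(lnFoldChange(sce3, integer(0), 5:8), "non-empty")
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bhOracle(p))
    expect_true(all(adj >= p))
  }
  expect_error(bhAdjust(c(0.1, NA)), "NA")
  expect_error(bhAdjust(c(0.1, 1.2)), "0, 1")
})

test_that("hurdle test handles degenerate genes and stays non-negative", {
  set.seed(11)
  m <- matrix(rpois(40 * 30, 2), 40, 30)
  m[1, ] <- 0                         # all-zero gene
  m[2, ] <- 5                         # all-detected gene
  sce <- normalizeLog(sceFromCounts(m + (m == 0 & row(m) > 2) * 0))
  ht <- hurdleTest(sce, 1:15, 16:30)
  expect_equal(ht$p_raw[1], 1)
  expect_equal(ht$df[2], 1L)          # discrete part degenerate
  expect_true(all(ht$stat >= 0))
  expect_true(all(ht$p_raw >= 0 & ht$p_raw <= 1))
  expect_error(hurdleTest(sce, 1:2, 3:30), "3 cells")
})

test_that("swapping groups negates lnFC and preserves p-values", {
  sim <- smallSim()
  sce <- normalizeLog(sim$sce)
  a <- colnames(sce)[sce$condition == "aged"][1:40]
  b <- colnames(sce)[sce$condition == "young"][1:40]
  deAB <- hurdleDE(sce, a, b)
  deBA <- hurdleDE(sce, b, a)
  expect_equal(deAB$lnFC, -deBA$lnFC, tolerance = 1e-10)
  expect_equal(deAB$p_raw, deBA$p_raw, tolerance = 1e-10)
})

test_that("appending all-zero genes shifts only the BH denominator", {
  set.seed(21)
  m <- matrix(rpois(30 * 40, 1.5), 30, 40)
  m[rowSums(m) == 0, 1] <- 1   # keep the baseline free of all-zero genes
  sceA <- normalizeLog(sceFromCounts(m))
  mB <- rbind(m, matrix(0, 10, 40))
  sceB <- normalizeLog(sceFromCounts(mB))
  deA <- hurdleDE(sceA, 1:20, 21:40)
  deB <- hurdleDE(sceB, 1:20, 21:40)
  expect_equal(deB$p_raw[1:30], deA$p_raw)
  expect_equal(deB$p_adj, bhOracle(deB$p_raw))
})

test_that("significance thresholds are strict inequalities", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   lnFC = c(0.5, 0.1, 0.5, -0.5),
                   p_adj = c(0.05, 0.01, 0.049, 0.049))
  out <- callSignificant(de)
  expect_identical(out$significant, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("planted DEGs are recovered with controlled error at 300 cells", {
  ## BH controls the expected false-discovery proportion; the realised FDP
  ## of a single run fluctuates binomially around it, so calls are pooled
  ## over three replicates and compared against 0.05 plus three binomial
  ## standard errors on the pooled call count
  nFalse <- 0; nCalls <- 0; recalls <- numeric(0)
  for (s in c(202, 203, 204)) {
    cfg <- simConfig(nCellsPerCondition = 1500, nGenes = 2000,
                     nMarkersPerSubtype = 10, nAgingDEGsPerSubtype = 80,
                     nSharedDEGs = 0, agingLnFCRange = c(0.3, 0.8),
                     seed = s)
    sim <- simulateCounts(cfg)
    sce <- normalizeLog(sim$sce)
    lab <- sce$trueLabel
    aged <- colnames(sce)[sce$condition == "aged" & lab == "capEC"]
    young <- colnames(sce)[sce$condition == "young" & lab == "capEC"]
    expect_gte(min(length(aged), length(young)), 260)
    de <- hurdleDE(sce, aged, young)
    planted <- names(which(agingEffects(sim$truth)[, "capEC"] != 0))
    called <- de$gene[de$significant]
    recalls <- c(recalls, mean(planted %in% called))
    nFalse <- nFalse + sum(!(called %in% planted))
    nCalls <- nCalls + length(called)
    ## planted signs recovered
    hit <- intersect(called, planted)
    expect_true(all(sign(agingEffects(sim$truth)[hit, "capEC"]) ==
                      sign(de$lnFC[match(hit, de$gene)])))
  }
  expect_gte(mean(recalls), 0.9)
  expect_lte(nFalse / nCalls, 0.05 + 3 * sqrt(0.05 * 0.95 / nCalls))
})

test_that("shared/specific classification matches a planted structure", {
  mk <- function(sig, dir) {
    data.frame(gene = paste0("g", 1:4), lnFC = dir,
               p_adj = ifelse(sig, 0.001, 0.5), significant = sig)
  }
  ## g1 significant in one table, g2 in all four (concordant), g3 in three
  ## with one sign flip, g4 nowhere
  deList <- list(
    aEC1 = mk(c(TRUE, TRUE, TRUE, FALSE), c(0.5, 0.4, 0.3, 0)),
    capEC = mk(c(FALSE, TRUE, TRUE, FALSE), c(0.1, 0.4, 0.3, 0)),
    vEC = mk(c(FALSE, TRUE, TRUE, FALSE), c(0.1, 0.4, -0.3, 0)),
    avEC = mk(c(FALSE, TRUE, FALSE, FALSE), c(0.1, 0.4, 0.3, 0)))
  cl <- classifySharedSpecific(deList)
  expect_identical(cl$category,
                   c("specific(1)", "shared>=3", "shared>=3", "none"))
  expect_identical(cl$concordant, c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(cl$nSubtypes, c(1, 4, 3, 0))
  expect_error(classifySharedSpecific(deList[1]), "at least two")
})
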