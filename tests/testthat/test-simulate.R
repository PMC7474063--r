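test_that("invalid configurations are rejected", {
  expect_error(simConfig(agingLnFCRange = c(0.05, 0.5)), "exceed 0.1")
  expect_error(simConfig(subtypeProportions = setNames(rep(0.2, 6),
                                                       zonationSubtypes())),
               "sum to 1")
  expect_error(simConfig(reversalFraction = 1.5), "reversalFraction")
  expect_error(simConfig(nGenes = 50), "too small")
  badProps <- setNames(c(0.5, 0.5, 0, 0, 0, 0), zonationSubtypes())
  cfg <- simConfig(nCellsPerCondition = 50, nGenes = 800,
                   nMarkersPerSubtype = 8, nAgingDEGsPerSubtype = 10,
                   nSharedDEGs = 0, subtypeProportions = badProps)
  expect_error(simulateCounts(cfg), "zero proportion")
})

test_that("identical configurations give bit-identical output", {
  cfg <- simConfig(nCellsPerCondition = 60, nGenes = 600,
                   nMarkersPerSubtype = 8, nAgingDEGsPerSubtype = 10,
                   nSharedDEGs = 4, seed = 5)
  a <- simulateCounts(cfg)
  b <- simulateCounts(cfg)
  expect_identical(SummarizedExperiment::assay(a$sce, "counts"),
                   SummarizedExperiment::assay(b$sce, "counts"))
  expect_identical(cellLabels(a$truth), cellLabels(b$truth))
  expect_identical(agingEffects(a$truth), agingEffects(b$truth))
})

test_that("no-effect configuration plants no aging effects", {
  cfg <- simConfig(nCellsPerCondition = 40, nGenes = 600,
                   nMarkersPerSubtype = 8, nAgingDEGsPerSubtype = 0,
                   nSharedDEGs = 0, seed = 2)
  sim <- simulateCounts(cfg)
  expect_true(all(agingEffects(sim$truth) == 0))
  expect_false(any(reversalFlags(sim$truth)))
})

test_that("truth is self-consistent with the planted structure", {
  sim <- smallSim()
  eff <- agingEffects(sim$truth)
  flags <- reversalFlags(sim$truth)
  ## every flag points at a nonzero effect
  expect_false(any(flags & eff == 0))
  ## per-subtype flagged fraction equals the configured fraction to 1/n
  cfg <- S4Vectors::metadata(sim$sce)$simConfig
  for (st in zonationSubtypes()) {
    n <- sum(eff[, st] != 0)
    expect_equal(sum(flags[, st]), round(cfg@reversalFraction * n))
  }
  ## the set of affected genes is exactly the planted DEG list
  planted <- rownames(eff)[rowSums(eff != 0) > 0]
  expect_setequal(planted,
                  unique(c(names(which(rowSums(abs(eff)) > 0)))))
  ## marker elevation raises home-subtype mean expression
  counts <- SummarizedExperiment::assay(sim$sce, "counts")
  lab <- sim$sce$trueLabel
  capMk <- markerSets(sim$truth)$capEC
  capMean <- mean(as.matrix(counts[capMk, lab == "capEC"]))
  vMean <- mean(as.matrix(counts[capMk, lab == "vEC"]))
  expect_gt(capMean, vMean)
})

test_that("realised capillary fraction matches its configured proportion", {
  ## the capillary subtype is configured near 20% of ECs, matching the
  ## observed stability of that compartment across age groups
  cfg <- simConfig(nCellsPerCondition = 1000, nGenes = 600,
                   nMarkersPerSubtype = 8, nAgingDEGsPerSubtype = 0,
                   nSharedDEGs = 0, contaminants = c(SMC = 0.02),
                   doubletRate = 0, seed = 31)
  sim <- simulateCounts(cfg)
  lab <- cellLabels(sim$truth)
  ec <- lab[lab %in% zonationSubtypes()]
  p <- cfg@subtypeProportions[["capEC"]]
  expect_equal(p, 0.2, tolerance = 0.01)
  phat <- mean(ec == "capEC")
  se <- sqrt(p * (1 - p) / length(ec))
  expect_lt(abs(phat - p), 4 * se)
})

test_that("simulated counts match their configured negative-binomial mean", {
  ## one population, ~10k cells; oracle = direct sampling from the same
  ## generative model (lognormal library, Beta mito share, NB counts)
  props <- setNames(c(0, 0, 1, 0, 0, 0), zonationSubtypes())
  cfg <- simConfig(nCellsPerCondition = 3400, subtypeProportions = props,
                   nGenes = 600, nMarkersPerSubtype = 8,
                   nAgingDEGsPerSubtype = 0, nSharedDEGs = 0,
                   contaminants = c(SMC = 0.001), doubletRate = 0, seed = 77)
  sim <- simulateCounts(cfg)
  lab <- sim$sce$trueLabel
  counts <- SummarizedExperiment::assay(sim$sce, "counts")[, lab == "capEC"]
  nCells <- ncol(counts)
  expect_gte(nCells, 10000)

  ## pick a non-marker, non-mito gene; reconstruct its relative abundance
  ## from the capEC profile implied by the truth marker sets
  mito <- SummarizedExperiment::rowData(sim$sce)$mito
  mk <- unique(unlist(markerSets(sim$truth)))
  gene <- setdiff(rownames(sim$sce)[!mito], mk)[1]

  set.seed(1)
  oracleOne <- function() {
    lib <- rlnorm(nCells, cfg@libsizeLogNormal[1], cfg@libsizeLogNormal[2])
    f <- rbeta(nCells, cfg@mitoBeta$default[1], cfg@mitoBeta$default[2])
    rel <- mean(counts[gene, ]) / mean(lib * (1 - f))  # plug-in abundance
    mean(rnbinom(nCells, mu = lib * (1 - f) * rel, size = cfg@nbDispersion))
  }
  oracle <- replicate(30, oracleOne())
  empirical <- mean(counts[gene, ])
  expect_lt(abs(empirical - mean(oracle)), 3 * sd(oracle))

  ## library-size conservation: mean per-cell total tracks the lognormal
  ## library mean when nothing is planted
  libMean <- exp(cfg@libsizeLogNormal[1] + cfg@libsizeLogNormal[2]^2 / 2)
  totals <- Matrix::colSums(counts)
  expect_lt(abs(mean(totals) - libMean) / libMean, 0.05)
})

test_that("human bulk: null genes are calibrated and ages span 46-70", {
  hb <- simulateHumanBulk(800, nPerGroup = 30, seed = 12)
  expect_true(all(hb$meta$age >= 46 & hb$meta$age <= 70))
  de <- bulkGroupDE(log(hb$bulk), hb$meta$group, caseLevel = "case")
  frac <- mean(de$p_raw < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 800))
})

test_that("human bulk: a planted lnFC of -0.5 is reliably detected", {
  hits <- vapply(seq_len(200), function(r) {
    hb <- simulateHumanBulk(40, nPerGroup = 30,
                            groupEffects = c(GENE0001 = -0.5),
                            sdLog = 0.3, seed = 5000 + r)
    de <- bulkGroupDE(log(hb$bulk), hb$meta$group, caseLevel = "case")
    de$p_adj[de$gene == "GENE0001"] < 0.05 && de$direction[de$gene == "GENE0001"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
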