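test_that("planted EC-enriched genes are recovered without false hits", {
  sim <- smallSim()
  sce <- normalizeLog(sim$sce)
  lab <- sim$sce$trueLabel
  prim <- ifelse(lab %in% zonationSubtypes(), "EC",
                 ifelse(grepl("^doublet:", lab), NA, lab))
  enr <- ecEnrichedGenes(sce, prim)
  sets <- markerSets(sim$truth)
  ## everything recovered must be genuinely endothelial-elevated: the
  ## planted EC-enriched program, the EC identity markers, or zonation
  ## markers shared between a home subtype and avEC (elevated in two of
  ## six subtypes, i.e. exactly twofold in pooled ECs by construction)
  trueEnriched <- c(sets$EC_enriched, sets$EC, sets$avEC)
  expect_true(all(enr$gene %in% trueEnriched))
  ## the planted program is recovered essentially in full
  expect_gte(mean(sets$EC_enriched %in% enr$gene), 0.9)
  expect_true(all(enr$lnFC > 0.7))
})

test_that("a gene at the enrichment boundary is excluded", {
  ## two genes: one exactly at lnFC 0.7 after the expm1-mean convention,
  ## one clearly above; only the latter passes the strict threshold
  nEC <- 200; nOther <- 200
  mA <- exp(0.7) * 2 - 1                      # EC expm1-mean for lnFC 0.7
  lc <- rbind(c(rep(log1p(mA), nEC), rep(log1p(1), nOther)),
              c(rep(log1p(12), nEC), rep(log1p(1), nOther)),
              rep(log1p(2), nEC + nOther))
  sce <- sceFromLogcounts(lc)
  labels <- c(rep("EC", nEC), rep("AC", nOther))
  lfc <- lnFoldChange(sce, which(labels == "EC"), which(labels != "EC"))
  expect_equal(unname(lfc[1]), 0.7)
  enr <- ecEnrichedGenes(sce, labels)
  expect_false("g001" %in% enr$gene)
  expect_true("g002" %in% enr$gene)
})

test_that("bulk group DE handles identical and planted contrasts", {
  set.seed(17)
  bulk <- matrix(rep(exp(rnorm(30, 3, 1)), 20), 30, 20)
  rownames(bulk) <- sprintf("G%02d", 1:30)
  groups <- rep(c("control", "case"), each = 10)
  de <- bulkGroupDE(bulk, groups, caseLevel = "case")
  expect_true(all(de$p_raw == 1))
  expect_true(all(de$effect == 0))
  expect_true(all(de$direction == 0))
  hb <- simulateHumanBulk(60, nPerGroup = 30,
                          groupEffects = c(GENE0007 = 0.8), seed = 23)
  de2 <- bulkGroupDE(log(hb$bulk), hb$meta$group, caseLevel = "case")
  expect_lt(de2$p_adj[de2$gene == "GENE0007"], 0.05)
  expect_gt(de2$effect[de2$gene == "GENE0007"], 0)
  expect_error(bulkGroupDE(bulk, rep("one", 20)), "two levels")
})

test_that("bulk age regression recovers a planted slope", {
  hb <- simulateHumanBulk(40, nPerGroup = 40,
                          ageSlopes = c(GENE0003 = 0.05), seed = 29)
  ar <- bulkAgeRegression(log(hb$bulk), hb$meta$age)
  est <- ar$slope[ar$gene == "GENE0003"]
  expect_lt(ar$p_adj[ar$gene == "GENE0003"], 0.05)
  expect_lt(abs(est - 0.05), 0.02)
  ## constant gene: slope 0, p 1
  bulk2 <- hb$bulk
  bulk2[1, ] <- 7
  ar2 <- bulkAgeRegression(bulk2, hb$meta$age)
  expect_equal(ar2$slope[1], 0)
  expect_equal(ar2$p_raw[1], 1)
  expect_error(bulkAgeRegression(hb$bulk, rep(50, ncol(hb$bulk))),
               "zero-variance")
})

test_that("BH scope covers only the tested genes", {
  hb <- simulateHumanBulk(50, nPerGroup = 10, seed = 31)
  sub <- rownames(hb$bulk)[1:20]
  deSub <- bulkGroupDE(log(hb$bulk), hb$meta$group, caseLevel = "case",
                       genes = sub)
  bigger <- rbind(log(hb$bulk), matrix(0, 30, ncol(hb$bulk)))
  rownames(bigger)[51:80] <- sprintf("PAD%02d", 1:30)
  deSub2 <- bulkGroupDE(bigger, hb$meta$group, caseLevel = "case",
                        genes = sub)
  expect_equal(deSub$p_adj, deSub2$p_adj)
})

test_that("concordance quadrants follow signs and flip antisymmetrically", {
  mouseDe <- data.frame(gene = c("Slc2a1", "Mfsd2a", "Flt1", "Klf6"),
                        lnFC = c(-0.4, -0.3, 0.5, 0.2))
  humanDe <- data.frame(gene = c("SLC2A1", "MFSD2A", "FLT1", "KLF6"),
                        direction = c(-1, -1, -1, 1),
                        p_adj = c(0.001, 0.01, 0.02, 0.4))
  map <- caseOrthologTable(mouseDe$gene)
  cc <- concordance(mouseDe, humanDe, map)
  expect_identical(cc$quadrant[match(c("Slc2a1", "Mfsd2a", "Flt1", "Klf6"),
                                     cc$mouse)],
                   c("concordant-down", "concordant-down", "discordant",
                     "human-ns"))
  ## negating the mouse effects swaps concordant and discordant
  neg <- mouseDe
  neg$lnFC <- -neg$lnFC
  cc2 <- concordance(neg, humanDe, map)
  sig <- cc$quadrant != "human-ns"
  expect_true(all((grepl("^concordant", cc$quadrant) &
                     cc2$quadrant == "discordant")[sig] |
                    (cc$quadrant == "discordant" &
                       grepl("^concordant", cc2$quadrant))[sig]))
})
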