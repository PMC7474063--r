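#' Construct a simulation configuration
#'
#' Builds a validated [SimConfig-class]. Defaults emulate the structure of a
#' brain vascular scRNA-seq aging study: three conditions (young, aged,
#' treated), six endothelial subtypes in the empirically observed
#' proportions (capillary ECs near 20%, capillary-venous the largest
#' fraction), a zonation marker panel of ~220 genes (44 per subtype over
#' five subtypes, with the arterial/venous subtype expressing a 50/50 union
#' of aEC1 and vEC markers), contaminating mural/glial populations, and
#' per-subtype planted aging effects of which 75% are reversed by
#' treatment.
#'
#' @param nCellsPerCondition endothelial cells per condition.
#' @param subtypeProportions named numeric(6) over
#'   `zonationSubtypes()`, summing to 1.
#' @param nGenes total gene count.
#' @param nMarkersPerSubtype zonation markers per subtype.
#' @param markerLogFC log elevation of markers in their home population.
#' @param nECEnrichedGenes genes elevated in all endothelial subtypes but
#'   no other population; may also carry aging effects.
#' @param ecEnrichedLogFC log elevation of the EC-enriched program (above
#'   the 0.7 lnFC enrichment threshold by a clear margin).
#' @param nAgingDEGsPerSubtype subtype-private planted aging DEGs.
#' @param nSharedDEGs aging DEGs planted in >= 3 subtypes.
#' @param agingLnFCRange interval for |lnFC| of planted effects; the lower
#'   bound must exceed 0.1.
#' @param agingFracUp fraction of planted effects that are upregulations.
#' @param reversalFraction fraction of affected genes reversed by treatment.
#' @param reversalStrength 1 = full reversion to young means.
#' @param nbDispersion shared negative-binomial dispersion theta.
#' @param libsizeLogNormal meanlog and sdlog of library size.
#' @param mitoBeta named list of Beta(a, b) parameters for per-cell
#'   mitochondrial fraction; must contain a "default" entry.
#' @param nMitoGenes number of mitochondrial genes.
#' @param contaminants named proportions of contaminant populations
#'   relative to the endothelial cell count.
#' @param contaminantMarkers marker genes per contaminant population.
#' @param doubletRate fraction of extra cells simulated as random pairs.
#' @param seed integer seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nCellsPerCondition = 300, nGenes = 800,
#'                  nMarkersPerSubtype = 10, nAgingDEGsPerSubtype = 40,
#'                  seed = 7)
#' cfg
#' @export
simConfig <- function(nCellsPerCondition = 3000,
                      subtypeProportions = c(aEC1 = 1141, aEC2 = 998,
                                             capEC = 1587, vcapEC = 3122,
                                             vEC = 798, avEC = 293) / 7939,
                      nGenes = 8000,
                      nMarkersPerSubtype = 44,
                      markerLogFC = log(4),
                      nECEnrichedGenes = 30,
                      ecEnrichedLogFC = 1.2,
                      nAgingDEGsPerSubtype = 300,
                      nSharedDEGs = 40,
                      agingLnFCRange = c(0.3, 0.8),
                      agingFracUp = 0.68,
                      reversalFraction = 0.75,
                      reversalStrength = 1,
                      nbDispersion = 10,
                      libsizeLogNormal = c(log(3500), 0.35),
                      mitoBeta = list(default = c(2.5, 47.5)),
                      nMitoGenes = 13,
                      contaminants = c(SMC = 0.05, PC = 0.03,
                                       MG = 0.10, AC = 0.08),
                      contaminantMarkers = 5,
                      doubletRate = 0.01,
                      seed = 1) {
  new("SimConfig",
      nCellsPerCondition = as.integer(nCellsPerCondition),
      subtypeProportions = subtypeProportions,
      nGenes = as.integer(nGenes),
      nMarkersPerSubtype = as.integer(nMarkersPerSubtype),
      markerLogFC = markerLogFC,
      nECEnrichedGenes = as.integer(nECEnrichedGenes),
      ecEnrichedLogFC = ecEnrichedLogFC,
      nAgingDEGsPerSubtype = as.integer(nAgingDEGsPerSubtype),
      nSharedDEGs = as.integer(nSharedDEGs),
      agingLnFCRange = agingLnFCRange,
      agingFracUp = agingFracUp,
      reversalFraction = reversalFraction,
      reversalStrength = reversalStrength,
      nbDispersion = nbDispersion,
      libsizeLogNormal = libsizeLogNormal,
      mitoBeta = mitoBeta,
      nMitoGenes = as.integer(nMitoGenes),
      contaminants = contaminants,
      contaminantMarkers = as.integer(contaminantMarkers),
      doubletRate = doubletRate,
      seed = as.integer(seed))
}

simConditions <- c("young", "aged", "treated")

#' Simulate a truth-labelled single-cell count matrix
#'
#' Draws UMI counts as negative binomial with mean
#' `libsize_c * relative_expression(gene, population, condition)`. Marker
#' genes are elevated by `exp(markerLogFC)` in their home population;
#' endothelial-wide and contaminant identity markers by
#' `exp(2 * markerLogFC)`. Planted aging DEGs shift the mean by
#' `exp(lnFC)` in the aged condition; genes flagged as reversed revert
#' toward young means in the treated condition. Mitochondrial genes are
#' flagged and receive a per-cell Beta-distributed share of the library.
#' Doublets are sums of two randomly paired cells' rate vectors from
#' different populations.
#'
#' @param config a [SimConfig-class].
#' @return list with `sce`, a
#'   [SingleCellExperiment::SingleCellExperiment] (sparse `counts` assay,
#'   `colData` condition/batch/true label, `rowData` mitochondrial flag)
#'   and `truth`, a [GroundTruth-class].
#' @examples
#' sim <- simulateCounts(simConfig(nCellsPerCondition = 120, nGenes = 400,
#'                                 nMarkersPerSubtype = 8,
#'                                 nAgingDEGsPerSubtype = 20,
#'                                 nSharedDEGs = 5, seed = 1))
#' sim$sce
#' sim$truth
#' @export
simulateCounts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@nAgingDEGsPerSubtype > 0L &&
      any(config@subtypeProportions == 0))
    stop("cannot plant per-subtype aging DEGs in a subtype with zero proportion")
  set.seed(config@seed)

  nG <- config@nGenes
  nMito <- config@nMitoGenes
  geneIds <- c(if (nMito > 0) sprintf("mt-gene%05d", seq_len(nMito)),
               sprintf("gene%05d", seq_len(nG - nMito) + nMito))
  mito <- c(rep(TRUE, nMito), rep(FALSE, nG - nMito))
  names(mito) <- geneIds

  ## baseline relative expression; mito genes normalised separately so the
  ## Beta-drawn mitochondrial fraction is exact in expectation
  relRaw <- rlnorm(nG, meanlog = 0, sdlog = 1.5)
  names(relRaw) <- geneIds
  baseNonMito <- relRaw[!mito] / sum(relRaw[!mito])
  mitoProfile <- if (nMito > 0) relRaw[mito] / sum(relRaw[mito]) else numeric(0)

  ## marker and DEG genes are drawn from the upper-third expression band
  ## (above the 67th percentile: robustly detected genes, where marker and
  ## aging-DEG programs live in real data) but below the 97th percentile,
  ## so planted programs never ride on the few library-dominating genes
  ## whose shifts would leak into every other gene's normalised expression
  nonMitoIds <- geneIds[!mito]
  upperHalf <- nonMitoIds[baseNonMito > quantile(baseNonMito, 0.67) &
                            baseNonMito <= quantile(baseNonMito, 0.97)]
  contamNames <- names(config@contaminants)
  nPrivate <- 5L * config@nMarkersPerSubtype
  nPrimary <- (1L + length(contamNames)) * config@contaminantMarkers
  nEnr <- config@nECEnrichedGenes
  if (length(upperHalf) < nPrivate + nPrimary + nEnr)
    stop("nGenes too small: not enough well-expressed genes for marker programs")
  markerPool <- sample(upperHalf, nPrivate + nPrimary + nEnr)
  privateSubtypes <- c("aEC1", "aEC2", "capEC", "vcapEC", "vEC")
  markerSets <- list()
  idx <- 0L
  for (s in privateSubtypes) {
    markerSets[[s]] <- markerPool[idx + seq_len(config@nMarkersPerSubtype)]
    idx <- idx + config@nMarkersPerSubtype
  }
  half <- config@nMarkersPerSubtype %/% 2L
  markerSets[["avEC"]] <- c(head(markerSets[["aEC1"]], ceiling(config@nMarkersPerSubtype / 2)),
                            head(markerSets[["vEC"]], half))
  for (ct in c("EC", contamNames)) {
    markerSets[[ct]] <- markerPool[idx + seq_len(config@contaminantMarkers)]
    idx <- idx + config@contaminantMarkers
  }
  ecEnriched <- markerPool[idx + seq_len(nEnr)]
  markerSets[["EC_enriched"]] <- ecEnriched

  ## planted aging effects: shared genes hit >=3 subtypes with a common
  ## effect; private genes hit exactly one subtype. EC-enriched genes stay
  ## in the pool (half the shared DEGs draw from them when available),
  ## mirroring the functionally important endothelial genes whose aging
  ## changes the cross-species comparison is built on.
  degPool <- setdiff(upperHalf, setdiff(markerPool, ecEnriched))
  nNeeded <- config@nSharedDEGs + 6L * config@nAgingDEGsPerSubtype
  nSharedEnr <- min(config@nSharedDEGs %/% 2L, nEnr)
  if (length(setdiff(degPool, ecEnriched)) < nNeeded - nSharedEnr)
    stop("nGenes too small for the requested number of aging DEGs")
  degGenes <- c(if (nSharedEnr > 0) sample(ecEnriched, nSharedEnr),
                sample(setdiff(degPool, ecEnriched), nNeeded - nSharedEnr))
  agingEffects <- matrix(0, nG, 6L, dimnames = list(geneIds, SUBTYPES))
  drawEffect <- function(n) {
    mag <- runif(n, config@agingLnFCRange[1], config@agingLnFCRange[2])
    sgn <- ifelse(runif(n) < config@agingFracUp, 1, -1)
    mag * sgn
  }
  pos <- 0L
  if (config@nSharedDEGs > 0L) {
    sharedGenes <- degGenes[seq_len(config@nSharedDEGs)]
    pos <- config@nSharedDEGs
    eff <- drawEffect(config@nSharedDEGs)
    for (i in seq_along(sharedGenes)) {
      k <- sample(3:6, 1)
      subs <- sample(SUBTYPES, k)
      agingEffects[sharedGenes[i], subs] <- eff[i]
    }
  }
  for (s in SUBTYPES) {
    if (config@nAgingDEGsPerSubtype == 0L) break
    g <- degGenes[pos + seq_len(config@nAgingDEGsPerSubtype)]
    pos <- pos + config@nAgingDEGsPerSubtype
    agingEffects[g, s] <- drawEffect(config@nAgingDEGsPerSubtype)
  }

  ## reversal flags: exactly round(fraction * affected) per subtype
  reversalFlags <- matrix(FALSE, nG, 6L, dimnames = list(geneIds, SUBTYPES))
  for (s in SUBTYPES) {
    aff <- which(agingEffects[, s] != 0)
    k <- round(config@reversalFraction * length(aff))
    if (k > 0) reversalFlags[sample(aff, k), s] <- TRUE
  }

  ## per-population relative profiles (non-mito genes, each summing to 1);
  ## identity markers are part of the profile, so they are renormalised in,
  ## while condition effects are applied on top without renormalisation to
  ## keep planted lnFC interpretable
  elevate <- function(ids, lfc) {
    p <- baseNonMito
    p[ids] <- p[ids] * exp(lfc)
    p / sum(p)
  }
  profiles <- list()
  for (s in SUBTYPES)
    profiles[[s]] <- elevate(c(markerSets[[s]], markerSets[["EC"]], ecEnriched),
                             c(rep(config@markerLogFC, length(markerSets[[s]])),
                               rep(2 * config@markerLogFC, length(markerSets[["EC"]])),
                               rep(config@ecEnrichedLogFC, nEnr)))
  for (ct in contamNames)
    profiles[[ct]] <- elevate(markerSets[[ct]], 2 * config@markerLogFC)

  condMult <- function(pop, cond) {
    m <- rep(1, sum(!mito))
    names(m) <- nonMitoIds
    if (!(pop %in% SUBTYPES) || cond == "young") return(m)
    eff <- agingEffects[nonMitoIds, pop]
    if (cond == "aged") return(m * exp(eff))
    rev <- reversalFlags[nonMitoIds, pop]
    eff[rev] <- eff[rev] * (1 - config@reversalStrength)
    m * exp(eff)
  }

  mitoPars <- function(pop) {
    if (pop %in% names(config@mitoBeta)) config@mitoBeta[[pop]]
    else config@mitoBeta[["default"]]
  }

  theta <- config@nbDispersion
  blocks <- list()       # sparse count blocks
  rateBlocks <- list()   # per-cell rate vectors kept for doublet synthesis
  labels <- character()
  conds <- character()

  sampleBlock <- function(n, pop, cond) {
    lib <- rlnorm(n, config@libsizeLogNormal[1], config@libsizeLogNormal[2])
    f <- rbeta(n, mitoPars(pop)[1], mitoPars(pop)[2])
    relNM <- profiles[[pop]] * condMult(pop, cond)
    rate <- matrix(0, nG, n, dimnames = list(geneIds, NULL))
    rate[nonMitoIds, ] <- outer(relNM, lib * (1 - f))
    if (nMito > 0) rate[geneIds[mito], ] <- outer(mitoProfile, lib * f)
    rate
  }
  drawCounts <- function(rate) {
    cnt <- matrix(rnbinom(length(rate), mu = rate, size = theta),
                  nrow(rate), ncol(rate), dimnames = dimnames(rate))
    methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
  }

  for (cond in simConditions) {
    nSub <- as.vector(stats::rmultinom(1, config@nCellsPerCondition,
                                       config@subtypeProportions))
    names(nSub) <- SUBTYPES
    nCont <- round(config@contaminants * config@nCellsPerCondition)
    condRates <- list()
    condLabels <- character()
    for (pop in c(SUBTYPES, contamNames)) {
      n <- if (pop %in% SUBTYPES) nSub[[pop]] else nCont[[pop]]
      if (n == 0) next
      r <- sampleBlock(n, pop, cond)
      condRates[[length(condRates) + 1L]] <- r
      condLabels <- c(condLabels, rep(pop, n))
    }
    rateMat <- do.call(cbind, condRates)
    nDoub <- round(config@doubletRate * ncol(rateMat))
    if (nDoub > 0) {
      i <- sample(ncol(rateMat), nDoub, replace = TRUE)
      j <- vapply(i, function(ii) {
        cand <- which(condLabels != condLabels[ii])
        if (length(cand) == 0) sample(ncol(rateMat), 1) else
          cand[sample(length(cand), 1)]
      }, integer(1))
      rateMat <- cbind(rateMat, rateMat[, i, drop = FALSE] +
                                rateMat[, j, drop = FALSE])
      pair <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "+"),
                     condLabels[i], condLabels[j])
      condLabels <- c(condLabels, paste0("doublet:", pair))
    }
    blocks[[cond]] <- drawCounts(rateMat)
    labels <- c(labels, condLabels)
    conds <- c(conds, rep(cond, length(condLabels)))
  }

  counts <- do.call(cbind, blocks)
  cellIds <- sprintf("cell%06d", seq_len(ncol(counts)))
  colnames(counts) <- cellIds
  names(labels) <- names(conds) <- cellIds

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      condition = unname(conds),
      batch = rep(c("batch1", "batch2"), length.out = length(conds)),
      trueLabel = unname(labels),
      row.names = cellIds),
    rowData = S4Vectors::DataFrame(mito = unname(mito), row.names = geneIds))
  S4Vectors::metadata(sce)$simConfig <- config

  truth <- new("GroundTruth",
               cellLabels = labels,
               cellConditions = conds,
               agingEffects = agingEffects,
               reversalFlags = reversalFlags,
               markerSets = markerSets)
  list(sce = sce, truth = truth)
}

#' Zonation marker matrix implied by a simulation truth
#'
#' Builds the binary genes x subtypes indicator over the union of the six
#' subtypes' true marker sets, for use by [fitAssignmentModel()].
#'
#' @param truth a [GroundTruth-class].
#' @return a [ZonationMarkers-class].
#' @export
zonationMarkersFromTruth <- function(truth) {
  sets <- markerSets(truth)[SUBTYPES]
  genes <- sort(unique(unlist(sets)))
  ind <- sapply(sets, function(g) as.numeric(genes %in% g))
  rownames(ind) <- genes
  new("ZonationMarkers", indicator = ind)
}

#' Simulate human-like bulk expression with planted group and age effects
#'
#' Log-normal expression per gene per sample on a TPM-like scale, with a
#' binary diagnosis/age-group label, a continuous age covariate drawn
#' uniformly over 46-70 years, and optional planted effects: `groupEffects`
#' adds lnFC to case samples; `ageSlopes` adds a linear trend in (age -
#' mean age) on the log scale.
#'
#' @param genes character vector of gene symbols, or a single integer count
#'   (symbols are then GENE0001, ...).
#' @param nPerGroup samples per group (>= 2).
#' @param groupEffects named numeric, gene -> lnFC in cases vs controls.
#' @param ageSlopes named numeric, gene -> per-year log-scale slope.
#' @param sdLog residual standard deviation on the log scale.
#' @param ageRange numeric(2) range of sampled ages in years.
#' @param seed integer seed.
#' @return list with `bulk` (genes x samples matrix), `meta` (data.frame of
#'   sample, group, age) and `effects`/`slopes` recording the planted truth.
#' @examples
#' hb <- simulateHumanBulk(50, nPerGroup = 10,
#'                         groupEffects = c(GENE0001 = -0.5), seed = 3)
#' dim(hb$bulk)
#' @export
simulateHumanBulk <- function(genes, nPerGroup = 30,
                              groupEffects = numeric(0),
                              ageSlopes = numeric(0),
                              sdLog = 0.3, ageRange = c(46, 70),
                              seed = 1) {
  if (is.numeric(genes) && length(genes) == 1L)
    genes <- sprintf("GENE%04d", seq_len(genes))
  if (nPerGroup < 2) stop("nPerGroup must be at least 2")
  stopifnot(all(names(groupEffects) %in% genes),
            all(names(ageSlopes) %in% genes))
  set.seed(as.integer(seed))
  nG <- length(genes)
  n <- 2L * nPerGroup
  group <- rep(c("control", "case"), each = nPerGroup)
  age <- runif(n, ageRange[1], ageRange[2])
  baseLog <- rnorm(nG, log(50), 1)
  names(baseLog) <- genes
  eff <- setNames(rep(0, nG), genes)
  eff[names(groupEffects)] <- groupEffects
  slp <- setNames(rep(0, nG), genes)
  slp[names(ageSlopes)] <- ageSlopes
  mu <- outer(baseLog, rep(1, n)) +
    outer(eff, as.numeric(group == "case")) +
    outer(slp, age - mean(ageRange))
  bulk <- exp(mu + matrix(rnorm(nG * n, 0, sdLog), nG, n))
  sampleIds <- sprintf("sample%03d", seq_len(n))
  dimnames(bulk) <- list(genes, sampleIds)
  meta <- data.frame(sample = sampleIds, group = group, age = age,
                     stringsAsFactors = FALSE)
  list(bulk = bulk, meta = meta, effects = eff, slopes = slp)
}

#' Synthetic disease gene lists with a controlled DEG overlap
#'
#' Convenience generator for overrepresentation testing: one list per
#' disease, each drawing `round(overlap * size)` genes from `degSet` and
#' the rest from the remaining universe.
#'
#' @param universe character vector of (human) gene symbols.
#' @param degSet subset of `universe` to enrich for.
#' @param overlap named numeric of per-disease overlap fractions.
#' @param size genes per disease list.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
simulateDiseaseGeneLists <- function(universe, degSet,
                                     overlap = c(AD = 0.4, stroke = 0.1,
                                                 PD = 0.0),
                                     size = 60, seed = 1) {
  set.seed(as.integer(seed))
  degSet <- intersect(degSet, universe)
  rest <- setdiff(universe, degSet)
  lapply(overlap, function(f) {
    kIn <- min(round(f * size), length(degSet))
    sort(c(sample(degSet, kIn), sample(rest, size - kIn)))
  })
}

#' Trivial mouse-to-human ortholog table
#'
#' One-to-one symbol-case mapping (mouse `Abcb1a` style to human `ABCB1A`
#' style), the baseline used by simulated cross-species runs.
#'
#' @param genes mouse gene symbols.
#' @return data.frame with columns `mouse` and `human`.
#' @export
caseOrthologTable <- function(genes) {
  data.frame(mouse = genes, human = toupper(genes), stringsAsFactors = FALSE)
}
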