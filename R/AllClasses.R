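#' @import methods
#' @importFrom stats quantile rnbinom rlnorm rbeta runif rnorm pchisq pnorm
#'   p.adjust lm coef var sd median setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

SUBTYPES <- c("aEC1", "aEC2", "capEC", "vcapEC", "vEC", "avEC")

#' Simulation configuration
#'
#' Parameters of the synthetic single-cell data generator. Defaults emulate
#' the structure of a two-age-group (plus treated) brain vascular scRNA-seq
#' study: six endothelial subtypes along the arteriovenous axis with graded
#' marker programs, contaminating non-endothelial populations, and planted
#' per-subtype aging effects of which a fixed fraction is reversed by
#' treatment.
#'
#' @slot nCellsPerCondition integer; endothelial cells simulated per
#'   condition (young, aged, treated). Contaminant populations add cells on
#'   top, in proportion to this number.
#' @slot subtypeProportions named numeric(6) summing to one; multinomial
#'   probabilities of the six subtypes (aEC1, aEC2, capEC, vcapEC, vEC,
#'   avEC).
#' @slot nGenes total number of genes (including mitochondrial and marker
#'   genes).
#' @slot nMarkersPerSubtype markers per subtype; avEC carries no private
#'   program but a 50/50 union of aEC1 and vEC markers.
#' @slot markerLogFC natural-log elevation of a marker gene in its home
#'   subtype.
#' @slot nECEnrichedGenes genes elevated in all six endothelial subtypes
#'   relative to every other population (beyond the identity markers);
#'   these genes can also carry aging effects, emulating functionally
#'   important endothelial genes that change with age.
#' @slot ecEnrichedLogFC log elevation of the EC-enriched program.
#' @slot nAgingDEGsPerSubtype subtype-private aging DEGs planted per subtype.
#' @slot nSharedDEGs aging DEGs planted jointly in three or more subtypes.
#' @slot agingLnFCRange numeric(2); |lnFC| of planted aging effects is drawn
#'   uniformly from this interval. The lower bound must exceed 0.1 so every
#'   planted effect clears the significance magnitude threshold.
#' @slot agingFracUp fraction of planted aging effects that are
#'   upregulations.
#' @slot reversalFraction fraction of each subtype's affected genes whose
#'   aging effect is reversed by treatment.
#' @slot reversalStrength 1 resets reversed genes fully to young means;
#'   values in (0,1) revert them partially.
#' @slot nbDispersion negative-binomial size parameter theta
#'   (var = mu + mu^2/theta), shared across genes.
#' @slot libsizeLogNormal numeric(2); meanlog and sdlog of per-cell library
#'   size.
#' @slot mitoBeta named list of numeric(2) Beta parameters of the per-cell
#'   mitochondrial fraction; entry "default" applies to populations without
#'   their own entry.
#' @slot nMitoGenes number of mitochondrial genes.
#' @slot contaminants named numeric; proportion of each contaminating
#'   population relative to the endothelial count.
#' @slot contaminantMarkers markers per contaminant population.
#' @slot doubletRate fraction of extra cells simulated as sums of two
#'   randomly paired cells' rate vectors.
#' @slot seed integer seed; identical configurations give bit-identical
#'   output.
#' @seealso [simConfig()], [simulateCounts()]
#' @export
setClass("SimConfig", representation(
  nCellsPerCondition = "integer",
  subtypeProportions = "numeric",
  nGenes = "integer",
  nMarkersPerSubtype = "integer",
  markerLogFC = "numeric",
  nECEnrichedGenes = "integer",
  ecEnrichedLogFC = "numeric",
  nAgingDEGsPerSubtype = "integer",
  nSharedDEGs = "integer",
  agingLnFCRange = "numeric",
  agingFracUp = "numeric",
  reversalFraction = "numeric",
  reversalStrength = "numeric",
  nbDispersion = "numeric",
  libsizeLogNormal = "numeric",
  mitoBeta = "list",
  nMitoGenes = "integer",
  contaminants = "numeric",
  contaminantMarkers = "integer",
  doubletRate = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  p <- object@subtypeProportions
  if (length(p) != 6L || !identical(names(p), SUBTYPES))
    msg <- c(msg, "subtypeProportions must be a named 6-vector over the six subtypes")
  if (abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "subtypeProportions must sum to 1 within 1e-9")
  if (any(p < 0)) msg <- c(msg, "subtypeProportions must be non-negative")
  r <- object@agingLnFCRange
  if (length(r) != 2L || r[1] > r[2])
    msg <- c(msg, "agingLnFCRange must be an ordered interval")
  if (length(r) == 2L && r[1] <= 0.1)
    msg <- c(msg, "agingLnFCRange lower bound must exceed 0.1")
  if (object@reversalFraction < 0 || object@reversalFraction > 1)
    msg <- c(msg, "reversalFraction must lie in [0,1]")
  if (object@reversalStrength <= 0 || object@reversalStrength > 1)
    msg <- c(msg, "reversalStrength must lie in (0,1]")
  if (object@agingFracUp < 0 || object@agingFracUp > 1)
    msg <- c(msg, "agingFracUp must lie in [0,1]")
  if (object@doubletRate < 0 || object@doubletRate > 1)
    msg <- c(msg, "doubletRate must lie in [0,1]")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be positive")
  if (object@markerLogFC <= 0) msg <- c(msg, "markerLogFC must be positive")
  if (object@nCellsPerCondition < 1L)
    msg <- c(msg, "nCellsPerCondition must be at least 1")
  if (!("default" %in% names(object@mitoBeta)))
    msg <- c(msg, "mitoBeta must contain a 'default' entry")
  if (length(object@libsizeLogNormal) != 2L || object@libsizeLogNormal[2] < 0)
    msg <- c(msg, "libsizeLogNormal must be (meanlog, sdlog) with sdlog >= 0")
  ## planted structure draws from a band of roughly 30% of the
  ## non-mitochondrial genes (67th-97th expression percentiles)
  need <- 5L * object@nMarkersPerSubtype +
    (1L + length(object@contaminants)) * object@contaminantMarkers +
    object@nECEnrichedGenes + object@nSharedDEGs +
    6L * object@nAgingDEGsPerSubtype
  if (0.30 * (object@nGenes - object@nMitoGenes) < need)
    msg <- c(msg, "nGenes too small for the requested marker/DEG structure")
  if (length(msg)) msg else TRUE
})

#' Simulation ground truth
#'
#' Truth labels emitted alongside a simulated dataset: per-cell population
#' labels, planted per-(gene, subtype) aging effects, treatment-reversal
#' flags and the true marker sets. This is the acceptance surface for
#' parameter-recovery tests.
#'
#' @slot cellLabels character named by cell barcode; a subtype name, a
#'   contaminant population name, or "doublet:<parentA>+<parentB>" naming
#'   the two populations a doublet was drawn from.
#' @slot cellConditions character named by cell barcode; "young", "aged" or
#'   "treated".
#' @slot agingEffects genes x 6 numeric matrix of true aging lnFC (0 where
#'   unaffected).
#' @slot reversalFlags genes x 6 logical matrix; TRUE where the planted
#'   effect is reverted under treatment.
#' @slot markerSets named list of character vectors: the true marker genes
#'   of each subtype and contaminant population.
#' @export
setClass("GroundTruth", representation(
  cellLabels = "character",
  cellConditions = "character",
  agingEffects = "matrix",
  reversalFlags = "matrix",
  markerSets = "list"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!identical(dim(object@agingEffects), dim(object@reversalFlags)))
    msg <- c(msg, "agingEffects and reversalFlags must share dimensions")
  if (any(object@reversalFlags & object@agingEffects == 0))
    msg <- c(msg, "every reversal flag must point at a nonzero aging effect")
  if (!identical(names(object@cellLabels), names(object@cellConditions)))
    msg <- c(msg, "cellLabels and cellConditions must cover the same cells")
  if (length(msg)) msg else TRUE
})

#' Arteriovenous zonation marker matrix
#'
#' Binary genes x subtypes indicator of zonation-dependent marker genes used
#' by the probabilistic subtype assignment. A gene may mark several subtypes
#' (the arterial/venous subtype is described by arterial plus venous
#' markers).
#'
#' @slot indicator binary matrix with gene rownames and the six subtype
#'   colnames.
#' @export
setClass("ZonationMarkers", representation(indicator = "matrix"))

setValidity("ZonationMarkers", function(object) {
  ind <- object@indicator
  msg <- character()
  if (is.null(rownames(ind)) || anyDuplicated(rownames(ind)))
    msg <- c(msg, "indicator must have unique gene rownames")
  if (is.null(colnames(ind)) || ncol(ind) < 2L)
    msg <- c(msg, "indicator must have at least two named subtype columns")
  if (!all(ind %in% c(0, 1)))
    msg <- c(msg, "indicator entries must be 0/1")
  if (any(colSums(ind) < 1))
    msg <- c(msg, "every subtype column needs at least one marker")
  if (length(msg)) msg else TRUE
})

#' Probabilistic subtype assignment result
#'
#' @slot posterior cells x subtypes row-stochastic matrix of posterior
#'   membership probabilities (from the last run for consensus results).
#' @slot label factor of argmax subtype per cell.
#' @slot runs cells x runs character matrix of per-run labels.
#' @slot consistent logical per cell; TRUE when all runs agree.
#' @slot logLik final observed-data log-likelihood of each run.
#' @slot converged logical per run.
#' @export
setClass("AssignmentResult", representation(
  posterior = "matrix",
  label = "factor",
  runs = "matrix",
  consistent = "logical",
  logLik = "numeric",
  converged = "logical"
))

setValidity("AssignmentResult", function(object) {
  msg <- character()
  rs <- rowSums(object@posterior)
  if (any(abs(rs - 1) > 1e-6))
    msg <- c(msg, "posterior rows must sum to 1 within 1e-6")
  if (nrow(object@posterior) != length(object@label))
    msg <- c(msg, "label length must match posterior rows")
  if (length(msg)) msg else TRUE
})

#' Cell quality-control report
#'
#' @slot nCellsIn,nCellsOut,nGenesIn,nGenesOut matrix dimensions before and
#'   after filtering.
#' @slot ruleCounts named integer; cells hit by each removal rule (a cell
#'   failing several rules is counted under each, but only once in
#'   nCellsOut accounting).
#' @export
setClass("QCReport", representation(
  nCellsIn = "integer", nCellsOut = "integer",
  nGenesIn = "integer", nGenesOut = "integer",
  ruleCounts = "integer"
))

setValidity("QCReport", function(object) {
  msg <- character()
  if (object@nCellsOut > object@nCellsIn || object@nGenesOut > object@nGenesIn)
    msg <- c(msg, "filtered dimensions cannot exceed input dimensions")
  if (length(msg)) msg else TRUE
})

#' Treatment-reversal report for one subtype
#'
#' Counts of aging-significant up/down genes, how many are reversed under
#' treatment, the constructed chance levels, one-sided one-proportion
#' z-tests against those chance levels, and the lnFC-lnFC regression of the
#' treated-vs-aged on the aged-vs-young contrast.
#'
#' @slot subtype subtype name.
#' @slot counts data.frame with one row per direction ("up", "down"):
#'   n, k (reversed), p0 (chance level), z, p.
#' @slot chanceUp,chanceDown fractions of all tested genes moving up/down in
#'   the treated-vs-aged contrast regardless of significance.
#' @slot regression list with slope, r2, p and n of the lnFC-lnFC fit.
#' @slot perGene data.frame of eligible genes with both contrasts' lnFC and
#'   the reversed flag.
#' @export
setClass("ReversalReport", representation(
  subtype = "character",
  counts = "data.frame",
  chanceUp = "numeric",
  chanceDown = "numeric",
  regression = "list",
  perGene = "data.frame"
))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,",
      object@nCellsPerCondition, "ECs per condition x 3 conditions\n")
  cat("  subtype proportions:",
      paste(sprintf("%s=%.3f", SUBTYPES, object@subtypeProportions),
            collapse = " "), "\n")
  cat(sprintf("  %d aging DEGs/subtype (+%d shared), lnFC in [%.2f, %.2f], %.0f%% reversed\n",
              object@nAgingDEGsPerSubtype, object@nSharedDEGs,
              object@agingLnFCRange[1], object@agingLnFCRange[2],
              100 * object@reversalFraction))
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@cellLabels), "cells,",
      nrow(object@agingEffects), "genes\n")
  cat("  affected (gene,subtype) pairs:", sum(object@agingEffects != 0),
      "of which reversed:", sum(object@reversalFlags), "\n")
})

setMethod("show", "ZonationMarkers", function(object) {
  cat("ZonationMarkers:", nrow(object@indicator), "genes x",
      ncol(object@indicator), "subtypes; markers per subtype:",
      paste(colSums(object@indicator), collapse = ", "), "\n")
})

setMethod("show", "AssignmentResult", function(object) {
  cat("AssignmentResult:", length(object@label), "cells,",
      ncol(object@runs), "run(s)\n")
  print(table(object@label))
  cat(sprintf("  consistent: %d/%d (%.1f%%)\n", sum(object@consistent),
              length(object@consistent),
              100 * mean(object@consistent)))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: cells %d -> %d, genes %d -> %d\n",
              object@nCellsIn, object@nCellsOut,
              object@nGenesIn, object@nGenesOut))
  for (nm in names(object@ruleCounts))
    cat("  ", nm, ": ", object@ruleCounts[[nm]], " cells\n", sep = "")
})

setMethod("show", "ReversalReport", function(object) {
  cat("ReversalReport [", object@subtype, "]\n", sep = "")
  print(object@counts, row.names = FALSE)
  cat(sprintf("  regression: slope=%.3f r2=%.3f p=%.3g (n=%d)\n",
              object@regression$slope, object@regression$r2,
              object@regression$p, object@regression$n))
})
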