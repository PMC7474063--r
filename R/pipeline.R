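.pipelineDefaults <- function() {
  list(
    outdir = "zonage_out",
    seed = 1,
    stages = list(simulate = TRUE, qc = TRUE, assign = TRUE, de = TRUE,
                  reverse = TRUE, enrich = TRUE, concord = TRUE),
    simulate = list(nCellsPerCondition = 400, nGenes = 1700,
                    nMarkersPerSubtype = 10, nAgingDEGsPerSubtype = 60,
                    nSharedDEGs = 10, reversalFraction = 0.75),
    qc = list(minCells = 3, pctLow = 0.05, pctHigh = 0.95, mitoMax = 0.2,
              scale = 1e4, dualHighFactor = 0.5),
    assign = list(nRuns = 3, theta = 10, tol = 1e-4, maxIter = 500,
                  jitterSd = 0.3, minCellsPerSubtype = 10),
    de = list(alpha = 0.05, lnfcMin = 0.1, minCellsPerGroup = 3),
    reverse = list(alpha = 0.05),
    enrich = list(diseaseLists = NULL, orthologMap = NULL, adjust = FALSE),
    concord = list(nPerGroup = 30, sdLog = 0.3, lnfcMin = 0.7,
                   mode = "group")
  )
}

## deterministic per-stage seeds: stage-indexed offsets from the global seed
.stageSeed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "qc", "assign", "de", "reverse",
                        "enrich", "concord"))
  as.integer(seed) + 1000L * idx
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills every missing entry
#' from the defaults, and rejects unknown keys (misspellings are errors,
#' not warnings) and out-of-range values. An empty file yields the full
#' default configuration.
#'
#' @param config YAML path or list.
#' @return the normalised configuration list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- .pipelineDefaults()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  simKeys <- setdiff(names(formals(simConfig)), "seed")
  sectionKeys <- lapply(defaults, names)
  sectionKeys$simulate <- simKeys
  out <- defaults
  for (nm in names(config)) {
    if (is.list(defaults[[nm]])) {
      bad <- setdiff(names(config[[nm]]), sectionKeys[[nm]])
      if (length(bad))
        stop("unknown key(s) in section '", nm, "': ",
             paste(bad, collapse = ", "))
      out[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]])
    } else {
      out[[nm]] <- config[[nm]]
    }
  }
  q <- out$qc
  if (q$mitoMax < 0 || q$mitoMax > 1) stop("qc$mitoMax must lie in [0, 1]")
  if (q$pctLow < 0 || q$pctHigh > 1 || q$pctLow >= q$pctHigh)
    stop("qc percentile bounds must satisfy 0 <= pctLow < pctHigh <= 1")
  if (!is.null(out$simulate$reversalFraction) &&
      (out$simulate$reversalFraction < 0 || out$simulate$reversalFraction > 1))
    stop("simulate$reversalFraction must lie in [0, 1]")
  if (out$assign$nRuns < 2) stop("assign$nRuns must be at least 2")
  if (!out$concord$mode %in% c("group", "age"))
    stop("concord$mode must be 'group' or 'age'")
  out
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, qc, assign, de,
#' reverse, enrich, concord — with a plain-TSV contract between stages:
#' each stage reads the previous stage's files from `outdir` and writes
#' its own. A manifest records every output file's MD5 hash together with
#' the seeds and parameters, so a rerun with an identical configuration
#' reproduces identical hashes. A failing stage aborts with its partial
#' outputs renamed to `*.partial`.
#'
#' @param config configuration list or YAML path (see [validateConfig()]).
#' @param seed optional override of the configured global seed.
#' @return invisibly, the manifest data.frame (file, stage, md5).
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "zonage-demo")
#' mf <- runPipeline(list(outdir = out,
#'                        simulate = list(nCellsPerCondition = 150,
#'                                        nGenes = 500,
#'                                        nMarkersPerSubtype = 8,
#'                                        nAgingDEGsPerSubtype = 30)))
#' head(mf)
#' }
#' @export
runPipeline <- function(config = list(), seed = NULL) {
  cfg <- validateConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- data.frame(file = character(), stage = character(),
                         stringsAsFactors = FALSE)
  stages <- c("simulate", "qc", "assign", "de", "reverse", "enrich",
              "concord")
  for (stage in stages) {
    if (!isTRUE(cfg$stages[[stage]])) next
    before <- list.files(outdir, recursive = TRUE)
    res <- tryCatch({
      switch(stage,
             simulate = .stageSimulate(cfg),
             qc = .stageQC(cfg),
             assign = .stageAssign(cfg),
             de = .stageDE(cfg),
             reverse = .stageReverse(cfg),
             enrich = .stageEnrich(cfg),
             concord = .stageConcord(cfg))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      newFiles <- setdiff(list.files(outdir, recursive = TRUE), before)
      for (f in newFiles)
        file.rename(file.path(outdir, f),
                    file.path(outdir, paste0(f, ".partial")))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(res))
    }
    manifest <- rbind(manifest,
                      data.frame(file = res, stage = stage,
                                 stringsAsFactors = FALSE))
  }
  manifest$md5 <- unname(tools::md5sum(file.path(outdir, manifest$file)))
  info <- list(seed = cfg$seed,
               package_version = as.character(utils::packageVersion("zonage")),
               stages_run = manifest$stage[!duplicated(manifest$stage)],
               parameters = cfg[setdiff(names(cfg), "outdir")])
  yaml::write_yaml(info, file.path(outdir, "run_info.yaml"))
  .writeTsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}

.stageSimulate <- function(cfg) {
  args <- cfg$simulate
  args$seed <- .stageSeed(cfg$seed, "simulate")
  sim <- do.call(simConfig, args)
  res <- simulateCounts(sim)
  d <- file.path(cfg$outdir, "counts")
  write10xTriplet(res$sce, d)
  truth <- res$truth
  writeZonationMarkers(zonationMarkersFromTruth(truth),
                       file.path(cfg$outdir, "zonation_markers.tsv"))
  sets <- markerSets(truth)
  prim <- sets[setdiff(names(sets), c(SUBTYPES, "EC_enriched"))]
  .writeTsv(data.frame(type = rep(names(prim), lengths(prim)),
                       gene = unlist(prim, use.names = FALSE)),
            file.path(cfg$outdir, "primary_markers.tsv"))
  eff <- agingEffects(truth)
  aff <- which(eff != 0, arr.ind = TRUE)
  .writeTsv(data.frame(gene = rownames(eff)[aff[, 1]],
                       subtype = colnames(eff)[aff[, 2]],
                       lnFC = eff[aff],
                       reversed = reversalFlags(truth)[aff]),
            file.path(cfg$outdir, "truth_aging_effects.tsv"))
  .stageLog("simulate", "%d genes x %d cells", nrow(res$sce), ncol(res$sce))
  c(file.path("counts", c("matrix.mtx", "features.tsv", "barcodes.tsv",
                          "cells.tsv")),
    "zonation_markers.tsv", "primary_markers.tsv",
    "truth_aging_effects.tsv")
}

.stageQC <- function(cfg) {
  sce <- read10xTriplet(file.path(cfg$outdir, "counts"))
  q <- cfg$qc
  sce <- filterGenesMinCells(sce, q$minCells)
  res <- qcFilterCells(sce, q$pctLow, q$pctHigh, q$mitoMax)
  sce <- normalizeLog(res$sce, q$scale)
  markers <- read.delim(file.path(cfg$outdir, "primary_markers.tsv"),
                        stringsAsFactors = FALSE)
  markerTable <- split(markers$gene, markers$type)
  typing <- assignPrimaryCellTypes(sce, markerTable, q$dualHighFactor)
  d <- file.path(cfg$outdir, "qc")
  write10xTriplet(sce, d)
  .writeTsv(data.frame(barcode = colnames(sce),
                       primaryType = as.character(typing$label),
                       excluded = typing$excluded),
            file.path(cfg$outdir, "primary_types.tsv"))
  rep <- res$report
  .writeTsv(data.frame(metric = c("cells_in", "cells_out", "genes_in",
                                  "genes_out", names(rep@ruleCounts)),
                       value = c(rep@nCellsIn, rep@nCellsOut, rep@nGenesIn,
                                 rep@nGenesOut, unname(rep@ruleCounts))),
            file.path(cfg$outdir, "qc_report.tsv"))
  .stageLog("qc", "cells %d -> %d; genes %d -> %d", rep@nCellsIn,
            rep@nCellsOut, rep@nGenesIn, rep@nGenesOut)
  c(file.path("qc", c("matrix.mtx", "features.tsv", "barcodes.tsv",
                      "cells.tsv")),
    "primary_types.tsv", "qc_report.tsv")
}

.loadQCed <- function(cfg) {
  sce <- read10xTriplet(file.path(cfg$outdir, "qc"))
  normalizeLog(sce, cfg$qc$scale)
}

.stageAssign <- function(cfg) {
  sce <- .loadQCed(cfg)
  types <- read.delim(file.path(cfg$outdir, "primary_types.tsv"),
                      stringsAsFactors = FALSE)
  ec <- types$barcode[!types$excluded & !is.na(types$primaryType) &
                        types$primaryType == "EC"]
  markers <- readZonationMarkers(file.path(cfg$outdir,
                                           "zonation_markers.tsv"))
  a <- cfg$assign
  base <- .stageSeed(cfg$seed, "assign")
  res <- consensusAssign(sce[, ec], markers, nRuns = a$nRuns,
                         seeds = base + seq_len(a$nRuns) - 1L,
                         theta = a$theta, tol = a$tol,
                         maxIter = a$maxIter, jitterSd = a$jitterSd)
  out <- data.frame(barcode = ec,
                    subtype = as.character(subtypeLabels(res)),
                    consistent = consistentCells(res),
                    round(posteriorProbs(res), 6))
  .writeTsv(out, file.path(cfg$outdir, "assignments.tsv"))
  .stageLog("assign", "%d ECs, %.1f%% consistent", length(ec),
            100 * mean(res@consistent))
  "assignments.tsv"
}

.deGroups <- function(cfg) {
  sce <- .loadQCed(cfg)
  asg <- read.delim(file.path(cfg$outdir, "assignments.tsv"),
                    stringsAsFactors = FALSE)
  asg <- asg[asg$consistent, ]
  list(sce = sce, asg = asg)
}

.stageDE <- function(cfg) {
  g <- .deGroups(cfg)
  sce <- g$sce
  cond <- setNames(sce$condition, colnames(sce))
  files <- character()
  for (st in unique(g$asg$subtype)) {
    cells <- g$asg$barcode[g$asg$subtype == st]
    young <- cells[cond[cells] == "young"]
    aged <- cells[cond[cells] == "aged"]
    treated <- cells[cond[cells] == "treated"]
    if (min(length(young), length(aged), length(treated)) <
        cfg$de$minCellsPerGroup) next
    deA <- hurdleDE(sce, aged, young, cfg$de$alpha, cfg$de$lnfcMin)
    deT <- hurdleDE(sce, treated, aged, cfg$de$alpha, cfg$de$lnfcMin)
    fa <- paste0("de_age_", st, ".tsv")
    ft <- paste0("de_treat_", st, ".tsv")
    writeDETable(deA, file.path(cfg$outdir, fa))
    writeDETable(deT, file.path(cfg$outdir, ft))
    files <- c(files, fa, ft)
    .stageLog("de", "%s: %d significant aging DEGs", st, sum(deA$significant))
  }
  if (!length(files)) stop("no subtype had enough cells in all conditions")
  ## EC-enrichment table for the cross-species stage
  types <- read.delim(file.path(cfg$outdir, "primary_types.tsv"),
                      stringsAsFactors = FALSE)
  keep <- !types$excluded & !is.na(types$primaryType)
  enr <- ecEnrichedGenes(sce[, types$barcode[keep]],
                         types$primaryType[keep],
                         lnfcMin = cfg$concord$lnfcMin)
  .writeTsv(enr, file.path(cfg$outdir, "ec_enriched.tsv"))
  c(files, "ec_enriched.tsv")
}

.deFiles <- function(cfg, prefix) {
  fs <- list.files(cfg$outdir, pattern = paste0("^de_", prefix, "_.*\\.tsv$"))
  setNames(fs, sub(paste0("^de_", prefix, "_(.*)\\.tsv$"), "\\1", fs))
}

.stageReverse <- function(cfg) {
  ageFiles <- .deFiles(cfg, "age")
  rows <- list()
  for (st in names(ageFiles)) {
    deA <- readDETable(file.path(cfg$outdir, ageFiles[[st]]))
    ft <- file.path(cfg$outdir, paste0("de_treat_", st, ".tsv"))
    if (!file.exists(ft)) next
    rep <- reversalReport(deA, readDETable(ft), subtype = st,
                          alpha = cfg$reverse$alpha)
    s <- reversalSummary(rep)
    s$slope <- rep@regression$slope
    s$r2 <- rep@regression$r2
    s$p_slope <- rep@regression$p
    rows[[st]] <- s
  }
  .writeTsv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            file.path(cfg$outdir, "reversal_summary.tsv"))
  .stageLog("reverse", "%d subtypes summarised", length(rows))
  "reversal_summary.tsv"
}

.stageEnrich <- function(cfg) {
  ageFiles <- .deFiles(cfg, "age")
  degSets <- list()
  universes <- list()
  map <- if (!is.null(cfg$enrich$orthologMap))
    readOrthologMap(cfg$enrich$orthologMap)
  else data.frame(mouse = character(), human = character())
  for (st in names(ageFiles)) {
    de <- readDETable(file.path(cfg$outdir, ageFiles[[st]]))
    degSets[[st]] <- mapOrthologs(de$gene[de$significant], map)$mapped$human
    universes[[st]] <- mapOrthologs(de$gene, map)$mapped$human
  }
  degSets <- degSets[lengths(degSets) > 0]
  if (!length(degSets)) stop("no significant DEGs to test for enrichment")
  if (!is.null(cfg$enrich$diseaseLists)) {
    dl <- readDiseaseLists(cfg$enrich$diseaseLists)
  } else {
    ref <- names(which.max(lengths(degSets)))
    dl <- simulateDiseaseGeneLists(universes[[ref]], degSets[[ref]],
                                   seed = .stageSeed(cfg$seed, "enrich"))
  }
  em <- enrichmentMatrix(degSets, dl, universes, adjust = cfg$enrich$adjust)
  .writeTsv(em, file.path(cfg$outdir, "enrichment.tsv"))
  .stageLog("enrich", "%d subtype x disease tests", nrow(em))
  "enrichment.tsv"
}

.stageConcord <- function(cfg) {
  ageFiles <- .deFiles(cfg, "age")
  enr <- read.delim(file.path(cfg$outdir, "ec_enriched.tsv"),
                    stringsAsFactors = FALSE)
  degs <- list()
  for (st in names(ageFiles)) {
    de <- readDETable(file.path(cfg$outdir, ageFiles[[st]]))
    degs[[st]] <- de[de$significant & de$gene %in% enr$gene,
                     c("gene", "lnFC")]
  }
  mouseDe <- do.call(rbind, degs)
  mouseDe <- mouseDe[!duplicated(mouseDe$gene), , drop = FALSE]
  if (nrow(mouseDe) == 0) stop("no EC-enriched significant DEGs to compare")
  map <- caseOrthologTable(mouseDe$gene)
  ## planted human effects: alternate concordant / discordant so the
  ## concordance table exercises every quadrant
  eff <- mouseDe$lnFC * rep_len(c(1, -1), nrow(mouseDe))
  names(eff) <- toupper(mouseDe$gene)
  hb <- simulateHumanBulk(toupper(mouseDe$gene),
                          nPerGroup = cfg$concord$nPerGroup,
                          groupEffects = eff,
                          ageSlopes = if (cfg$concord$mode == "age")
                            eff / 12 else numeric(0),
                          sdLog = cfg$concord$sdLog,
                          seed = .stageSeed(cfg$seed, "concord"))
  humanDe <- if (cfg$concord$mode == "group")
    bulkGroupDE(log(hb$bulk), hb$meta$group, caseLevel = "case")
  else bulkAgeRegression(log(hb$bulk), hb$meta$age)
  cc <- concordance(mouseDe, humanDe, map)
  .writeTsv(cc, file.path(cfg$outdir, "concordance.tsv"))
  .writeTsv(data.frame(gene = rownames(hb$bulk), round(hb$bulk, 4),
                       check.names = FALSE),
            file.path(cfg$outdir, "human_bulk.tsv"))
  .writeTsv(hb$meta, file.path(cfg$outdir, "human_meta.tsv"))
  .stageLog("concord", "%d genes compared, %d concordant", nrow(cc),
            sum(grepl("^concordant", cc$quadrant)))
  c("concordance.tsv", "human_bulk.tsv", "human_meta.tsv")
}
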