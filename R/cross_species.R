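#' Endothelial-enriched genes
#'
#' Runs the hurdle DE machinery for endothelial cells against all other
#' cell types pooled and retains genes with `lnFC > lnfcMin` (strictly;
#' the default 0.7 means at least twofold higher expression) and
#' BH-adjusted p < `alpha`.
#'
#' @param sce a SingleCellExperiment with a `logcounts` assay.
#' @param labels per-cell labels distinguishing `ecLabel` from everything
#'   else; cells with NA labels are ignored.
#' @param ecLabel the endothelial label (default "EC").
#' @param lnfcMin enrichment threshold on lnFC (default 0.7).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame with gene, lnFC, p_adj for the retained genes.
#' @export
ecEnrichedGenes <- function(sce, labels, ecLabel = "EC", lnfcMin = 0.7,
                            alpha = 0.05) {
  labels <- as.character(labels)
  ec <- colnames(sce)[!is.na(labels) & labels == ecLabel]
  other <- colnames(sce)[!is.na(labels) & labels != ecLabel]
  if (length(ec) == 0 || length(other) == 0)
    stop("labels must contain endothelial and non-endothelial cells")
  de <- hurdleDE(sce, ec, other)
  keep <- de$lnFC > lnfcMin & de$p_adj < alpha
  out <- de[keep, c("gene", "lnFC", "p_adj")]
  rownames(out) <- NULL
  out
}

#' Per-gene two-group bulk differential expression
#'
#' Welch (unequal-variance) two-sided t-test per gene of `caseLevel`
#' versus the other group, BH-adjusted across the tested genes only.
#' Genes with zero variance in both groups get effect 0 and p = 1.
#'
#' @param bulk genes x samples non-negative expression matrix (TPM-like).
#' @param groups character/factor per sample with exactly two levels.
#' @param caseLevel level whose mean enters the effect with positive sign
#'   (default the second sorted level).
#' @param genes optional subset of rownames to test (the mouse EC-enriched
#'   orthologs); defaults to all rows.
#' @return data.frame with gene, effect (case mean - control mean), t,
#'   p_raw, p_adj, direction.
#' @export
bulkGroupDE <- function(bulk, groups, caseLevel = NULL, genes = NULL) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("groups must have exactly two levels")
  if (is.null(caseLevel)) caseLevel <- lv[2]
  if (!caseLevel %in% lv) stop("caseLevel not found in groups")
  ctrl <- setdiff(lv, caseLevel)
  if (sum(groups == caseLevel) < 2 || sum(groups == ctrl) < 2)
    stop("need at least 2 samples per group")
  if (is.null(genes)) genes <- rownames(bulk)
  genes <- intersect(genes, rownames(bulk))
  a <- bulk[genes, groups == caseLevel, drop = FALSE]
  b <- bulk[genes, groups == ctrl, drop = FALSE]
  res <- t(vapply(seq_along(genes), function(i) {
    x <- a[i, ]; y <- b[i, ]
    eff <- mean(x) - mean(y)
    if (sd(x) == 0 && sd(y) == 0)
      return(c(effect = 0, t = 0, p = 1))
    tt <- stats::t.test(x, y, var.equal = FALSE)
    c(effect = eff, t = unname(tt$statistic), p = tt$p.value)
  }, numeric(3)))
  data.frame(gene = genes, effect = res[, "effect"], t = res[, "t"],
             p_raw = res[, "p"], p_adj = bhAdjust(res[, "p"]),
             direction = sign(res[, "effect"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene regression of bulk expression on age
#'
#' Ordinary least squares of expression on age per gene, two-sided t-test
#' on the slope, BH-adjusted across the tested genes.
#'
#' @param bulk genes x samples expression matrix.
#' @param ages numeric per sample with at least 3 distinct values.
#' @param genes optional subset of rownames to test.
#' @return data.frame with gene, slope, r2, p_raw, p_adj, direction.
#' @export
bulkAgeRegression <- function(bulk, ages, genes = NULL) {
  if (length(ages) != ncol(bulk)) stop("ages must cover all samples")
  if (var(ages) == 0) stop("zero-variance age vector")
  if (length(unique(ages)) < 3) stop("need at least 3 distinct ages")
  if (is.null(genes)) genes <- rownames(bulk)
  genes <- intersect(genes, rownames(bulk))
  res <- t(vapply(genes, function(g) {
    y <- bulk[g, ]
    if (sd(y) == 0) return(c(slope = 0, r2 = 0, p = 1))
    fit <- summary(lm(y ~ ages))
    c(slope = unname(fit$coefficients[2, 1]), r2 = fit$r.squared,
      p = unname(fit$coefficients[2, 4]))
  }, numeric(3)))
  data.frame(gene = genes, slope = res[, "slope"], r2 = res[, "r2"],
             p_raw = res[, "p"], p_adj = bhAdjust(res[, "p"]),
             direction = sign(res[, "slope"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-species concordance of differential expression
#'
#' Joins mouse DEGs (with their EC-enrichment filter already applied) to a
#' human bulk DE table via an ortholog map and classifies each pair:
#' `concordant-up` / `concordant-down` when the human change is
#' significant (adjusted p < `alpha`) with the same sign as the mouse
#' lnFC, `discordant` when significant with the opposite sign, and
#' `human-ns` otherwise.
#'
#' @param mouseDe data.frame with columns gene and lnFC (significant
#'   mouse DEGs, e.g. from [hurdleDE()] filtered to significant,
#'   EC-enriched genes).
#' @param humanDe data.frame with columns gene, direction and p_adj (from
#'   [bulkGroupDE()] or [bulkAgeRegression()]).
#' @param map ortholog table with columns `mouse` and `human`.
#' @param alpha human significance threshold (default 0.05).
#' @return data.frame with mouse gene, human gene, mouse lnFC, human
#'   direction and p_adj, and the quadrant label.
#' @export
concordance <- function(mouseDe, humanDe, map, alpha = 0.05) {
  orth <- mapOrthologs(mouseDe$gene, map)$mapped
  joined <- merge(orth, humanDe, by.x = "human", by.y = "gene")
  joined <- merge(joined, mouseDe[, c("gene", "lnFC")],
                  by.x = "mouse", by.y = "gene")
  hsig <- joined$p_adj < alpha & joined$direction != 0
  quadrant <- ifelse(!hsig, "human-ns",
                     ifelse(sign(joined$lnFC) == joined$direction,
                            ifelse(joined$direction > 0, "concordant-up",
                                   "concordant-down"),
                            "discordant"))
  out <- data.frame(mouse = joined$mouse, human = joined$human,
                    lnFC_mouse = joined$lnFC,
                    direction_human = joined$direction,
                    p_adj_human = joined$p_adj,
                    quadrant = quadrant, stringsAsFactors = FALSE)
  out[order(out$mouse), , drop = FALSE]
}
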