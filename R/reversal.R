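#' Per-gene reversal flags for a treated contrast
#'
#' Eligibility follows the aging contrast alone: every gene with
#' BH-adjusted p < `alpha` in the aged-vs-young table is eligible,
#' regardless of |lnFC| (deliberately laxer than the DEG significance
#' rule). An eligible gene is reversed when its treated-vs-aged lnFC has
#' the opposite sign to its aging lnFC; a treated lnFC of exactly zero
#' counts as not reversed.
#'
#' @param deAge DE table (aged vs young) from [hurdleDE()].
#' @param deTreat DE table (treated vs aged) over the same gene universe.
#' @param alpha eligibility threshold on the aging adjusted p (default
#'   0.05).
#' @return data.frame with columns gene, lnFC_age, lnFC_treat, eligible,
#'   direction (sign of the aging change for eligible genes) and reversed.
#' @export
reversalSets <- function(deAge, deTreat, alpha = 0.05) {
  if (!identical(sort(deAge$gene), sort(deTreat$gene)))
    stop("aged and treated DE tables must share the same gene universe")
  i <- match(deAge$gene, deTreat$gene)
  lfcA <- deAge$lnFC
  lfcT <- deTreat$lnFC[i]
  eligible <- deAge$p_adj < alpha & lfcA != 0
  reversed <- eligible & sign(lfcT) == -sign(lfcA) & lfcT != 0
  data.frame(gene = deAge$gene, lnFC_age = lfcA, lnFC_treat = lfcT,
             eligible = eligible,
             direction = ifelse(eligible, sign(lfcA), 0),
             reversed = reversed, stringsAsFactors = FALSE)
}

#' Chance levels of movement under treatment
#'
#' The constructed null of the reversal test: the proportions of ALL
#' tested genes whose treated-vs-aged lnFC is positive (`pUp`) or negative
#' (`pDown`), regardless of statistical significance. Genes with lnFC
#' exactly zero belong to neither, so `pUp + pDown <= 1`.
#'
#' @param deTreat DE table (treated vs aged) over the full tested gene
#'   universe for the subtype.
#' @return named numeric: `pUp`, `pDown`.
#' @export
chanceLevels <- function(deTreat) {
  c(pUp = mean(deTreat$lnFC > 0), pDown = mean(deTreat$lnFC < 0))
}

#' One-sided one-proportion z-test
#'
#' Tests whether an observed proportion k/n exceeds a fixed chance level
#' p0: `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)`, upper-tail standard
#' normal p-value.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param p0 chance level, strictly inside (0, 1).
#' @return named numeric: `z`, `p`.
#' @examples
#' reversalZTest(70, 100, 0.5)   # z = 4, p ~ 3.17e-5
#' @export
reversalZTest <- function(k, n, p0) {
  if (n < 1) stop("n must be at least 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("degenerate chance level p0; must be in (0, 1)")
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  c(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' lnFC-lnFC reversal regression
#'
#' Ordinary least squares of the treated-vs-aged lnFC on the aged-vs-young
#' lnFC over the eligible genes, with the two-sided t-test on the slope.
#' A slope near -1 with high r-squared indicates full transcriptomic
#' reversal.
#'
#' @param lnfcAge,lnfcTreat numeric vectors over the same >= 3 genes.
#' @return list with slope, r2, p and n.
#' @export
reversalRegression <- function(lnfcAge, lnfcTreat) {
  if (length(lnfcAge) != length(lnfcTreat))
    stop("lnFC vectors must have equal length")
  if (length(lnfcAge) < 3) stop("need at least 3 eligible genes")
  fit <- lm(lnfcTreat ~ lnfcAge)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(lnfcAge))
}

#' Full reversal report for one subtype
#'
#' Combines [reversalSets()], [chanceLevels()], [reversalZTest()] and
#' [reversalRegression()]: counts aging-up and aging-down eligible genes,
#' how many each direction has reversed, and tests each proportion against
#' its chance level — the chance of an up-gene being reversed (moving
#' down) is `pDown`, and of a down-gene `pUp`. An optional gene subset
#' (e.g. a functional pathway list) restricts which eligible genes are
#' counted without changing the eligibility logic or the chance levels.
#'
#' @inheritParams reversalSets
#' @param subtype label recorded in the report.
#' @param geneSubset optional character vector restricting the counted
#'   genes.
#' @return a [ReversalReport-class].
#' @export
reversalReport <- function(deAge, deTreat, subtype = "EC", alpha = 0.05,
                           geneSubset = NULL) {
  sets <- reversalSets(deAge, deTreat, alpha = alpha)
  ch <- chanceLevels(deTreat)
  counted <- sets[sets$eligible, ]
  if (!is.null(geneSubset)) counted <- counted[counted$gene %in% geneSubset, ]
  rows <- lapply(c(up = 1, down = -1), function(s) {
    sel <- counted[counted$direction == s, ]
    n <- nrow(sel)
    k <- sum(sel$reversed)
    p0 <- if (s > 0) unname(ch["pDown"]) else unname(ch["pUp"])
    zt <- if (n >= 1 && p0 > 0 && p0 < 1) reversalZTest(k, n, p0)
          else c(z = NA_real_, p = NA_real_)
    data.frame(direction = if (s > 0) "up" else "down", n = n, k = k,
               p0 = p0, z = unname(zt["z"]), p = unname(zt["p"]),
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  reg <- if (nrow(counted) >= 3)
    reversalRegression(counted$lnFC_age, counted$lnFC_treat)
  else list(slope = NA_real_, r2 = NA_real_, p = NA_real_,
            n = nrow(counted))
  new("ReversalReport", subtype = subtype, counts = counts,
      chanceUp = unname(ch["pUp"]), chanceDown = unname(ch["pDown"]),
      regression = reg, perGene = sets)
}

#' Summarise a reversal report as one table row per direction
#'
#' @param report a [ReversalReport-class].
#' @return data.frame with subtype, direction, n, k, fraction reversed,
#'   chance level, z and p.
#' @export
reversalSummary <- function(report) {
  cbind(subtype = report@subtype, report@counts,
        fraction = ifelse(report@counts$n > 0,
                          report@counts$k / report@counts$n, NA_real_))
}

#' Chance-corrected estimate of the reversed fraction
#'
#' The raw reversed proportion k/n mixes genuine reversal with chance sign
#' flips: a gene whose aging change is untouched by treatment still shows
#' an opposite-signed treated-vs-aged lnFC with probability close to the
#' chance level, so E(k/n) = f + (1 - f) p0. This inverts that relation,
#' pooling the up and down directions:
#' `f_hat = sum_d (k_d - n_d p0_d) / sum_d n_d (1 - p0_d)`,
#' clipped to \[0, 1\].
#'
#' @param report a [ReversalReport-class], or a list of them (pooled).
#' @return the estimated fraction of aging-significant genes whose change
#'   is genuinely reversed by treatment.
#' @export
reversalFractionEstimate <- function(report) {
  reports <- if (is.list(report)) report else list(report)
  num <- 0; den <- 0
  for (r in reports) {
    cnt <- r@counts
    ok <- cnt$n > 0 & !is.na(cnt$p0) & cnt$p0 < 1
    num <- num + sum(cnt$k[ok] - cnt$n[ok] * cnt$p0[ok])
    den <- den + sum(cnt$n[ok] * (1 - cnt$p0[ok]))
  }
  if (den == 0) return(NA_real_)
  min(max(num / den, 0), 1)
}
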