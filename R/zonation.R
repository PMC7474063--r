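## Negative-binomial log-likelihood kernel, dropping y-only terms:
## f(y, mu) = y log mu - (y + theta) log(mu + theta).
## Concave in log mu, which makes the per-gene Newton updates safe.
.nbKernel <- function(Y, logMu, theta) {
  Y * logMu - (Y + theta) * log(exp(logMu) + theta)
}

.nbConst <- function(Y, theta) {
  ## y-dependent constants of the NB pmf, summed per cell
  colSums(lgamma(Y + theta) - lgamma(theta) - lgamma(Y + 1) +
            theta * log(theta))
}

## One projected, backtracking Newton step on a per-gene parameter of the
## expected complete-data log-likelihood. `qFun(par)` returns the per-gene
## objective, `gFun`/`hFun` its gradient and (negative) curvature. Any gene
## whose objective would decrease has its step halved; this keeps the whole
## EM a generalised EM with a non-decreasing observed likelihood.
.newtonStep <- function(par, qFun, gFun, hFun, lower = -Inf) {
  q0 <- qFun(par)
  step <- gFun(par) / pmax(-hFun(par), 1e-8)
  new <- pmax(par + step, lower)
  for (i in 1:25) {
    bad <- qFun(new) < q0 - 1e-12
    if (!any(bad)) break
    new[bad] <- par[bad] + (new[bad] - par[bad]) / 2
  }
  new[qFun(new) < q0] <- par[qFun(new) < q0]
  new
}

#' Fit the probabilistic arteriovenous subtype assignment model
#'
#' One EM run of a six-component negative-binomial mixture over the
#' zonation marker genes. Under subtype t, the count of marker gene g in
#' cell c is NB with mean `s_c * beta_g * exp(delta_g * rho_gt)`, where
#' `s_c` is a marker-gene size factor (totals over the median total),
#' `beta_g` a baseline, `delta_g >= 0` the marker over-expression, and
#' `rho` the binary marker indicator. The E-step computes subtype
#' posteriors under a uniform prior; the M-step updates `beta` and `delta`
#' by damped Newton steps, so the observed log-likelihood never decreases.
#' The seed controls only the initialisation jitter (a per-gene
#' log-normal reweighting of the initial marker scores), which is what
#' makes multi-run consensus informative.
#'
#' @param sce a SingleCellExperiment of endothelial cells (counts assay);
#'   at least 20 cells.
#' @param markers a [ZonationMarkers-class]; at least one marker per
#'   subtype must be present in `sce`.
#' @param seed integer controlling EM initialisation.
#' @param theta fixed NB dispersion shared across marker genes.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations; non-convergence warns and returns
#'   the best-so-far fit flagged as unconverged.
#' @param jitterSd standard deviation of the log-normal initialisation
#'   jitter.
#' @return an [AssignmentResult-class]; `@logLik` holds the full iteration
#'   trace of this run.
#' @references The mixture follows the marker-indicator design of
#'   probabilistic cell-type assignment models for scRNA-seq, reduced to a
#'   fixed shared dispersion and a uniform prior.
#' @export
fitAssignmentModel <- function(sce, markers, seed = 1, theta = 10,
                               tol = 1e-4, maxIter = 500, jitterSd = 0.3) {
  if (ncol(sce) < 20) stop("need at least 20 endothelial cells")
  ind <- markerIndicator(markers)
  keep <- rownames(ind) %in% rownames(sce)
  if (any(colSums(ind[keep, , drop = FALSE]) < 1))
    stop("every subtype needs at least one marker present in the matrix")
  ind <- ind[keep, , drop = FALSE]
  Y <- as.matrix(SummarizedExperiment::assay(sce, "counts")[rownames(ind), ,
                                                            drop = FALSE])
  nT <- ncol(ind)
  tot <- colSums(Y)
  s <- tot / max(median(tot), 1)
  s <- pmax(s, 1e-8)
  logS <- log(s)

  set.seed(as.integer(seed))
  w <- exp(rnorm(nrow(Y), 0, jitterSd))          # gene-level: permutation-safe
  Ynorm <- sweep(Y, 2, s, "/")
  num <- t(Ynorm * w) %*% ind
  den <- colSums(ind * w)
  score <- sweep(num, 2, den, "/")
  P <- score + 0.01 * rowSums(score) / nT + 1e-8  # soft floor, uniform fallback
  P <- P / rowSums(P)

  b <- log(pmax(rowMeans(Ynorm), 1e-6))
  d <- rep(log(2), nrow(Y))
  const <- .nbConst(Y, theta)

  eStep <- function(b, d) {
    L <- matrix(0, ncol(Y), nT)
    for (t in seq_len(nT)) {
      logMu <- outer(b + d * ind[, t], rep(1, ncol(Y))) +
        matrix(logS, nrow(Y), ncol(Y), byrow = TRUE)
      L[, t] <- colSums(.nbKernel(Y, logMu, theta)) + const
    }
    mx <- apply(L, 1, max)
    E <- exp(L - mx)
    list(post = E / rowSums(E),
         ll = sum(log(rowSums(E)) + mx) - ncol(Y) * log(nT))
  }

  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    ## M-step: per-gene expected weights of being in a marked subtype
    wOn <- ind %*% t(P)                           # genes x cells
    wOff <- 1 - wOn
    qB <- function(bb) {
      muOffL <- outer(bb, rep(1, ncol(Y))) + matrix(logS, length(bb), ncol(Y), byrow = TRUE)
      rowSums(wOff * .nbKernel(Y, muOffL, theta) +
              wOn * .nbKernel(Y, muOffL + d, theta))
    }
    gradH <- function(bb, dd, which = "b") {
      muOff <- exp(outer(bb, rep(1, ncol(Y)))) * matrix(s, length(bb), ncol(Y), byrow = TRUE)
      muOn <- muOff * exp(dd)
      gOff <- theta * (Y - muOff) / (muOff + theta)
      gOn <- theta * (Y - muOn) / (muOn + theta)
      hOff <- -theta * muOff * (Y + theta) / (muOff + theta)^2
      hOn <- -theta * muOn * (Y + theta) / (muOn + theta)^2
      if (which == "b")
        list(g = rowSums(wOff * gOff + wOn * gOn),
             h = rowSums(wOff * hOff + wOn * hOn))
      else
        list(g = rowSums(wOn * gOn), h = rowSums(wOn * hOn))
    }
    gh <- gradH(b, d, "b")
    b <- .newtonStep(b, qB, function(x) gh$g, function(x) gh$h)
    qD <- function(dd) {
      muOffL <- outer(b, rep(1, ncol(Y))) + matrix(logS, length(b), ncol(Y), byrow = TRUE)
      rowSums(wOff * .nbKernel(Y, muOffL, theta) +
              wOn * .nbKernel(Y, muOffL + dd, theta))
    }
    gh <- gradH(b, d, "d")
    d <- .newtonStep(d, qD, function(x) gh$g, function(x) gh$h, lower = 0)

    es <- eStep(b, d)
    P <- es$post
    trace <- c(trace, es$ll)
    if (iter >= 2) {
      prev <- trace[iter - 1]
      if (es$ll < prev - 1e-6 * (abs(prev) + 1))
        warning("EM log-likelihood decreased at iteration ", iter)
      if (abs(es$ll - prev) < tol * (abs(prev) + 1)) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("EM did not converge in ", maxIter, " iterations; ",
            "returning best-so-far fit")

  rownames(P) <- colnames(sce)
  colnames(P) <- colnames(ind)
  lab <- factor(colnames(ind)[max.col(P, ties.method = "first")],
                levels = colnames(ind))
  names(lab) <- colnames(sce)
  new("AssignmentResult",
      posterior = P, label = lab,
      runs = matrix(as.character(lab), ncol = 1,
                    dimnames = list(colnames(sce), "run1")),
      consistent = setNames(rep(TRUE, ncol(sce)), colnames(sce)),
      logLik = trace, converged = converged)
}

#' Multi-seed consensus subtype assignment
#'
#' Runs [fitAssignmentModel()] once per seed and marks a cell consistent
#' when all runs give it the same label. Downstream subtype-level analyses
#' should use only consistent cells.
#'
#' @param sce a SingleCellExperiment of endothelial cells.
#' @param markers a [ZonationMarkers-class].
#' @param nRuns number of independent runs (>= 2).
#' @param seeds distinct integer seeds, one per run (default `1:nRuns`).
#' @param ... passed to [fitAssignmentModel()].
#' @return an [AssignmentResult-class]: `@posterior` and `@label` come from
#'   the final run, `@runs` holds all per-run labels, `@consistent` flags
#'   cells with identical labels across runs, and `@logLik` holds the final
#'   log-likelihood of each run.
#' @export
consensusAssign <- function(sce, markers, nRuns = 3, seeds = NULL, ...) {
  if (nRuns < 2) stop("nRuns must be at least 2")
  if (is.null(seeds)) seeds <- seq_len(nRuns)
  if (length(seeds) != nRuns || anyDuplicated(seeds))
    stop("seeds must be ", nRuns, " distinct integers")
  fits <- lapply(seeds, function(sd)
    fitAssignmentModel(sce, markers, seed = sd, ...))
  runs <- vapply(fits, function(f) as.character(subtypeLabels(f)),
                 character(ncol(sce)))
  dimnames(runs) <- list(colnames(sce), paste0("run", seq_len(nRuns)))
  consistent <- apply(runs, 1, function(r) length(unique(r)) == 1L)
  last <- fits[[nRuns]]
  new("AssignmentResult",
      posterior = posteriorProbs(last),
      label = subtypeLabels(last),
      runs = runs,
      consistent = consistent,
      logLik = vapply(fits, function(f) tail(f@logLik, 1), numeric(1)),
      converged = vapply(fits, function(f) f@converged, logical(1)))
}

#' @importFrom utils tail
NULL
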