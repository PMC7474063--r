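#' Map mouse genes to human orthologs
#'
#' Applies a (possibly one-to-many) symbol mapping table; genes absent
#' from the table are reported rather than silently dropped, and by
#' default fall back to the upper-case symbol convention (mouse `Mfsd2a`
#' to human `MFSD2A`).
#'
#' @param genes character vector of mouse symbols.
#' @param map data.frame with columns `mouse` and `human`; one row per
#'   mapping, duplicated mouse symbols expand to all targets.
#' @param fallbackCase map genes missing from the table by upper-casing
#'   (default TRUE).
#' @return list with `mapped` (data.frame mouse, human, source =
#'   "map"/"case") and `unmapped` (mouse symbols absent from the table;
#'   empty when they were all resolved by the fallback).
#' @export
mapOrthologs <- function(genes, map, fallbackCase = TRUE) {
  stopifnot(all(c("mouse", "human") %in% names(map)))
  if (any(!nzchar(map$human))) stop("ortholog map contains empty targets")
  hit <- map[map$mouse %in% genes, c("mouse", "human")]
  if (nrow(hit)) hit$source <- "map"
  missing <- setdiff(genes, map$mouse)
  if (fallbackCase && length(missing)) {
    fb <- data.frame(mouse = missing, human = toupper(missing),
                     source = "case", stringsAsFactors = FALSE)
    mapped <- rbind(hit, fb)
    unmapped <- character(0)
  } else {
    mapped <- hit
    unmapped <- missing
  }
  mapped <- mapped[order(match(mapped$mouse, genes)), , drop = FALSE]
  rownames(mapped) <- NULL
  list(mapped = mapped, unmapped = unmapped)
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail hypergeometric probability of observing at least the
#' realised overlap between a DEG set and a disease gene list within a
#' finite universe: `p = P(X >= k)` for
#' `X ~ Hypergeometric(N = |universe|, K = |disease in universe|,
#' n = |deg|)`. The tail is accumulated by summing exact PMF terms in
#' log-gamma arithmetic. Disease genes outside the universe are dropped
#' before testing.
#'
#' @param degSet character vector, a subset of `universe`.
#' @param diseaseSet character vector of disease-associated genes.
#' @param universe character vector, the background gene universe (all
#'   genes tested for differential expression).
#' @return named numeric: `k` (overlap), `K`, `n`, `N`, `p`.
#' @examples
#' hypergeomOverrep(letters[1:5], letters[c(2, 4, 6, 8)], letters[1:10])
#' @export
hypergeomOverrep <- function(degSet, diseaseSet, universe) {
  universe <- unique(universe)
  degSet <- unique(degSet)
  if (length(universe) == 0) stop("empty universe")
  if (length(degSet) == 0) stop("empty DEG set")
  if (!all(degSet %in% universe))
    stop("degSet must be a subset of the universe")
  diseaseSet <- intersect(unique(diseaseSet), universe)
  N <- length(universe)
  K <- length(diseaseSet)
  n <- length(degSet)
  k <- length(intersect(degSet, diseaseSet))
  ## P(X >= k) by log-space summation of C(K,i) C(N-K, n-i) / C(N,n)
  lo <- max(k, max(0L, n - (N - K)))
  hi <- min(K, n)
  if (lo > hi) {
    p <- if (k <= max(0L, n - (N - K))) 1 else 0
  } else {
    i <- lo:hi
    lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    m <- max(lt)
    p <- min(exp(m + log(sum(exp(lt - m)))), 1)
    if (k <= max(0L, n - (N - K))) p <- 1
  }
  c(k = k, K = K, n = n, N = N, p = p)
}

#' Disease overrepresentation matrix across subtypes
#'
#' Runs [hypergeomOverrep()] for every (subtype DEG set) x (disease list)
#' pair, using each subtype's tested gene universe as background. Raw
#' hypergeometric p-values are reported; an optional BH adjustment across
#' the whole matrix is off by default.
#'
#' @param degSets named list: subtype -> human DEG symbols.
#' @param diseaseLists named list: disease -> human gene symbols.
#' @param universe character vector or named list of per-subtype
#'   universes.
#' @param adjust BH-adjust across the subtype x disease matrix (default
#'   FALSE).
#' @return data.frame with subtype, disease, k, K, n, N, p (and p_adj when
#'   `adjust`).
#' @export
enrichmentMatrix <- function(degSets, diseaseLists, universe,
                             adjust = FALSE) {
  rows <- list()
  for (st in names(degSets)) {
    uni <- if (is.list(universe)) universe[[st]] else universe
    for (ds in names(diseaseLists)) {
      r <- hypergeomOverrep(degSets[[st]], diseaseLists[[ds]], uni)
      rows[[length(rows) + 1L]] <-
        data.frame(subtype = st, disease = ds, k = r["k"], K = r["K"],
                   n = r["n"], N = r["N"], p = r["p"],
                   row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- bhAdjust(out$p)
  out
}

#' Read two-column TSV gene lists
#'
#' `readDiseaseLists` expects columns `disease` and `gene` (symbols are
#' upper-cased); `readOrthologMap` expects `mouse` and `human`.
#'
#' @param path TSV file path.
#' @return a named list of character vectors, or a data.frame.
#' @export
readDiseaseLists <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("disease", "gene") %in% names(df)))
  lst <- split(toupper(df$gene), df$disease)
  if (any(lengths(lst) == 0)) stop("empty disease list in ", path)
  lst
}

#' @rdname readDiseaseLists
#' @export
readOrthologMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mouse", "human") %in% names(df)))
  df
}
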