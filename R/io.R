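#' Write a count matrix as a 10x-style triplet
#'
#' Emits `matrix.mtx` (MatrixMarket coordinate integer), `features.tsv`,
#' `barcodes.tsv`, plus a `cells.tsv` sidecar with the per-cell metadata
#' (condition, batch and, when present, the simulation truth label).
#' Everything is plain text, so a write/read round trip is lossless.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a
#'   `counts` assay and a logical `mito` column in `rowData`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [read10xTriplet()]
#' @export
write10xTriplet <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  m <- methods::as(m, "TsparseMatrix")
  ## deterministic MatrixMarket writer: column-major entry order, integer
  ## values, so identical matrices give byte-identical files
  o <- order(m@j, m@i)
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(nrow(m), ncol(m), length(m@x)),
             sprintf("%d %d %d", m@i[o] + 1L, m@j[o] + 1L,
                     as.integer(m@x[o])))
  writeLines(lines, file.path(dir, "matrix.mtx"))
  feat <- data.frame(id = rownames(sce),
                     mito = as.integer(SummarizedExperiment::rowData(sce)$mito))
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cd <- cbind(barcode = colnames(sce), cd)
  write.table(cd, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style triplet into a SingleCellExperiment
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` (and the
#' `cells.tsv` metadata sidecar when present), validating the MatrixMarket
#' header and that the declared dimensions match the sidecar files. Errors
#' name the offending file.
#'
#' @param dir directory holding the triplet.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay.
#' @export
read10xTriplet <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  ffeat <- file.path(dir, "features.tsv")
  fbar <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, ffeat, fbar))
    if (!file.exists(f)) stop("missing file: ", f)
  hdr <- readLines(mtx, n = 1L)
  if (!grepl("^%%MatrixMarket matrix coordinate (integer|real) general", hdr))
    stop("malformed MatrixMarket header in ", mtx, ": ", hdr)
  m <- Matrix::readMM(mtx)
  if (any(m@x < 0) || any(m@x != round(m@x)))
    stop("non-integer or negative entries in ", mtx)
  feat <- read.delim(ffeat, header = FALSE, stringsAsFactors = FALSE)
  bar <- readLines(fbar)
  if (nrow(feat) != nrow(m))
    stop(sprintf("matrix.mtx declares %d rows but %s has %d lines",
                 nrow(m), ffeat, nrow(feat)))
  if (length(bar) != ncol(m))
    stop(sprintf("matrix.mtx declares %d columns but %s has %d lines",
                 ncol(m), fbar, length(bar)))
  if (anyDuplicated(feat[[1]])) stop("duplicate gene identifiers in ", ffeat)
  if (anyDuplicated(bar)) stop("duplicate cell barcodes in ", fbar)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(feat[[1]], bar)
  mito <- if (ncol(feat) >= 2) as.logical(as.integer(feat[[2]]))
          else grepl("^mt-", feat[[1]], ignore.case = TRUE)
  cd <- S4Vectors::DataFrame(row.names = bar)
  fcells <- file.path(dir, "cells.tsv")
  if (file.exists(fcells)) {
    cells <- read.delim(fcells, stringsAsFactors = FALSE)
    if (!identical(cells$barcode, bar))
      stop("cells.tsv barcodes do not match barcodes.tsv")
    cd <- S4Vectors::DataFrame(cells[setdiff(names(cells), "barcode")],
                               row.names = bar)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = cd,
    rowData = S4Vectors::DataFrame(mito = mito, row.names = feat[[1]]))
}

#' Read or write a zonation marker matrix as TSV
#'
#' The TSV has a `gene` column followed by one 0/1 column per subtype.
#'
#' @param markers a [ZonationMarkers-class] (for writing).
#' @param path file path.
#' @return `readZonationMarkers` returns a [ZonationMarkers-class];
#'   `writeZonationMarkers` returns `path` invisibly.
#' @export
writeZonationMarkers <- function(markers, path) {
  ind <- markerIndicator(markers)
  df <- data.frame(gene = rownames(ind), ind, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeZonationMarkers
#' @export
readZonationMarkers <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ind <- as.matrix(df[setdiff(names(df), "gene")])
  rownames(ind) <- df$gene
  new("ZonationMarkers", indicator = ind)
}

#' Write a differential-expression table as TSV
#'
#' Fixed column order: gene, lnFC, p_raw, p_adj, pct_A, pct_B, significant.
#'
#' @param de a DE result data.frame from [hurdleDE()].
#' @param path file path.
#' @export
writeDETable <- function(de, path) {
  cols <- c("gene", "lnFC", "p_raw", "p_adj", "pct_A", "pct_B", "significant")
  write.table(as.data.frame(de)[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeDETable
#' @export
readDETable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
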