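#' Read a 10x-style count directory into a SingleCellExperiment
#'
#' Expects Matrix Market counts plus tab-separated metadata:
#' `matrix.mtx` (genes x cells), `genes.tsv` (one gene id per line),
#' `barcodes.tsv` (one cell barcode per line), `cells.tsv` (columns
#' `barcode`, `subject`, `cell_type`) and optionally `subjects.tsv`
#' (column `subject` plus the tested factor and covariates).
#'
#' @param dir directory containing the files.
#' @return a [SingleCellExperiment::SingleCellExperiment]; when
#'   `subjects.tsv` is present the per-subject table is attached as
#'   `metadata(sce)$design` (row names = subject).
#' @export
readCountsMTX <- function(dir) {
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "cells.tsv")
  paths <- file.path(dir, need)
  if (!all(file.exists(paths)))
    stop("missing input file(s): ",
         paste(need[!file.exists(paths)], collapse = ", "))
  counts <- as(Matrix::readMM(paths[1]), "CsparseMatrix")
  genes <- read.delim(paths[2], header = FALSE)[[1]]
  barcodes <- read.delim(paths[3], header = FALSE)[[1]]
  if (nrow(counts) != length(genes) || ncol(counts) != length(barcodes))
    stop("matrix dimensions do not match genes/barcodes files")
  dimnames(counts) <- list(genes, barcodes)
  cells <- read.delim(paths[4], header = TRUE)
  if (!all(c("barcode", "subject", "cell_type") %in% colnames(cells)))
    stop("cells.tsv needs columns barcode, subject, cell_type")
  idx <- match(barcodes, cells$barcode)
  if (anyNA(idx)) stop("barcodes missing from cells.tsv")
  sce <- SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(subject = as.character(cells$subject[idx]),
                        cell_type = as.character(cells$cell_type[idx]),
                        row.names = barcodes))
  subjPath <- file.path(dir, "subjects.tsv")
  if (file.exists(subjPath)) {
    subj <- read.delim(subjPath, header = TRUE)
    if (!"subject" %in% colnames(subj)) stop("subjects.tsv needs a 'subject' column")
    rownames(subj) <- subj$subject
    metadata(sce)$design <- subj[, setdiff(colnames(subj), "subject"), drop = FALSE]
  }
  sce
}

#' Write a SingleCellExperiment as a 10x-style count directory
#'
#' Inverse of [readCountsMTX()]; also writes `truth_Z.tsv` and
#' `truth_lfc.tsv` when the object carries simulation truth in its
#' metadata, and `subjects.tsv` when it carries a design.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with colData
#'   `subject` and `cell_type`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCountsMTX <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- .getCounts(sce)
  Matrix::writeMM(as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(colData(sce))
  cells <- data.frame(barcode = colnames(counts),
                      subject = cd$subject, cell_type = cd$cell_type)
  write.table(cells, file.path(dir, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  md <- metadata(sce)
  if (!is.null(md$design)) {
    subj <- data.frame(subject = rownames(md$design), md$design)
    write.table(subj, file.path(dir, "subjects.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(md$truthZ))
    write.table(md$truthZ, file.path(dir, "truth_Z.tsv"),
                sep = "\t", quote = FALSE)
  if (!is.null(md$truthLfc))
    write.table(md$truthLfc, file.path(dir, "truth_lfc.tsv"),
                sep = "\t", quote = FALSE)
  invisible(dir)
}
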