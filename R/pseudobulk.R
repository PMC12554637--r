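#' Filter genes expressed in too few cells
#'
#' Within each cell type, genes detected (nonzero count) in fewer than
#' `minCells` cells of that type are excluded from that cell type's
#' analysis. Because the joint model needs one DE-state vector per gene
#' across all cell types, downstream stages operate on the intersection of
#' genes passing the filter in every cell type (see `universe` in the
#' return value).
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a
#'   `counts` assay and colData columns `subject` and `cell_type`, or a
#'   (sparse) genes x cells count matrix plus `cellType`.
#' @param minCells minimum number of cells of a type in which a gene must
#'   be detected (default 10).
#' @param cellType per-cell type labels, only needed when `sce` is a bare
#'   matrix.
#'
#' @return a list with `keep` (genes x types logical matrix of per-type
#'   keep masks) and `universe` (character vector of genes kept in every
#'   cell type).
#' @export
filterLowExpression <- function(sce, minCells = 10, cellType = NULL) {
  .assertScalarNumber(minCells, "minCells", lower = 0)
  counts <- .getCounts(sce)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cellType)) cellType <- .getCellMeta(sce)$cell_type
  if (length(cellType) != ncol(counts))
    stop("'cellType' must have one entry per cell")
  types <- sort(unique(as.character(cellType)))
  ncells <- vapply(types, function(k)
    Matrix::rowSums(counts[, cellType == k, drop = FALSE] > 0), numeric(nrow(counts)))
  keep <- ncells >= minCells
  dimnames(keep) <- list(rownames(counts), types)
  dead <- colSums(keep) == 0
  if (any(dead))
    stop("all genes filtered out in cell type(s): ", paste(types[dead], collapse = ", "))
  list(keep = keep, universe = rownames(counts)[rowSums(keep) == ncol(keep)])
}

#' Aggregate single-cell counts into per-cell-type pseudo-bulk matrices
#'
#' For each cell type, cell-level counts are summed within each subject,
#' giving a genes x subjects matrix per type. Subject/type pairs with zero
#' cells are dropped from that type's matrix (not zero-filled) and recorded
#' in the result's `missingPairs`.
#'
#' @inheritParams filterLowExpression
#' @param design data.frame of per-subject variables; row names must be
#'   subject identifiers. If `NULL` (only for a `SingleCellExperiment` whose
#'   colData carries a `group` column) a single binary factor `A` is derived
#'   from `group`.
#' @param factorName column(s) of `design` holding the tested factor
#'   (default `"A"`).
#' @param covariateNames columns of `design` holding adjustment covariates.
#' @param subject per-cell subject labels when `sce` is a bare matrix.
#' @param cellType per-cell type labels when `sce` is a bare matrix.
#'
#' @return a [PseudoBulkSet-class] with raw sums filled (run
#'   [logNormalize()] next).
#' @export
aggregateCounts <- function(sce, design = NULL, factorName = "A",
                            covariateNames = character(0),
                            subject = NULL, cellType = NULL) {
  counts <- .getCounts(sce)
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  meta <- if (is.null(subject)) .getCellMeta(sce) else
    data.frame(subject = as.character(subject), cell_type = as.character(cellType))
  if (anyNA(meta$subject) || anyNA(meta$cell_type))
    stop("every cell needs a subject and a cell type")
  if (is.null(design)) {
    design <- if (is(sce, "SummarizedExperiment") && !is.null(metadata(sce)$design))
      metadata(sce)$design else .designFromColData(sce, factorName)
  }
  .checkDesign(design, factorName, covariateNames)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))

  subjectsAll <- if (all(unique(meta$subject) %in% rownames(design)))
    intersect(rownames(design), unique(meta$subject))
  else stop("cells reference subjects absent from the design table")
  types <- sort(unique(meta$cell_type))

  raw <- list(); subjects <- list()
  miss <- data.frame(subject = character(0), cell_type = character(0))
  for (k in types) {
    sel <- meta$cell_type == k
    subj <- factor(meta$subject[sel], levels = subjectsAll)
    # cells x subjects indicator; counts %*% ind sums columns per subject
    ind <- sparseMatrix(i = seq_len(sum(sel)), j = as.integer(subj),
                        x = 1, dims = c(sum(sel), length(subjectsAll)))
    m <- as.matrix(counts[, sel, drop = FALSE] %*% ind)
    colnames(m) <- subjectsAll
    present <- tabulate(subj, nbins = length(subjectsAll)) > 0
    if (any(!present))
      miss <- rbind(miss, data.frame(subject = subjectsAll[!present], cell_type = k))
    raw[[k]] <- m[, present, drop = FALSE]
    subjects[[k]] <- subjectsAll[present]
  }
  if (nrow(miss))
    warning(sprintf("%d (subject, cell type) pair(s) have no cells and were dropped per type",
                    nrow(miss)))
  new("PseudoBulkSet", raw = raw, norm = list(), subjects = subjects,
      design = design[subjectsAll, , drop = FALSE], factorName = factorName,
      covariateNames = covariateNames, geneIds = rownames(counts),
      missingPairs = miss)
}

#' Log-normalize pseudo-bulk matrices
#'
#' Library-size normalization followed by a natural-log transform, applied
#' per pseudo-bulk column: `Y = log(1 + raw / libsize * scaleFactor)` where
#' `libsize` is the column sum over retained genes. Zero counts map to zero
#' and the transform is monotone within a column.
#'
#' @param pb a [PseudoBulkSet-class] from [aggregateCounts()].
#' @param scaleFactor multiplicative rescaling applied after library-size
#'   division (default 1e4).
#' @param strict if `TRUE`, a zero library size is an error; otherwise the
#'   column (subject) is dropped from that cell type with a warning.
#'
#' @return the same `PseudoBulkSet` with the `norm` matrices filled.
#' @export
logNormalize <- function(pb, scaleFactor = 1e4, strict = FALSE) {
  stopifnot(is(pb, "PseudoBulkSet"))
  .assertScalarNumber(scaleFactor, "scaleFactor", lower = .Machine$double.eps)
  norm <- list()
  for (k in names(pb@raw)) {
    m <- pb@raw[[k]]
    lib <- colSums(m)
    if (any(lib == 0)) {
      if (strict) stop(sprintf("zero library size in cell type '%s'", k))
      warning(sprintf("dropping %d zero-library column(s) in cell type '%s'",
                      sum(lib == 0), k))
      pb@missingPairs <- rbind(pb@missingPairs,
        data.frame(subject = colnames(m)[lib == 0], cell_type = k))
      m <- m[, lib > 0, drop = FALSE]
      lib <- lib[lib > 0]
      pb@raw[[k]] <- m
      pb@subjects[[k]] <- colnames(m)
    }
    norm[[k]] <- log1p(sweep(m, 2, lib, "/") * scaleFactor)
  }
  pb@norm <- norm
  validObject(pb)
  pb
}

#' Log-normalize a cell-level count matrix
#'
#' Same transform as [logNormalize()] but applied per cell; used by the
#' cell-level t-test comparator. Sparsity is preserved (zeros map to zero).
#'
#' @param counts genes x cells count matrix (dense or `dgCMatrix`).
#' @param scaleFactor see [logNormalize()].
#' @return matrix of the same class and shape.
#' @export
normalizeCells <- function(counts, scaleFactor = 1e4) {
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) stop("cells with zero total count; filter them first")
  if (is(counts, "dgCMatrix")) {
    j <- rep.int(seq_len(ncol(counts)), diff(counts@p))
    counts@x <- log1p(counts@x / lib[j] * scaleFactor)
    counts
  } else {
    log1p(sweep(as.matrix(counts), 2, lib, "/") * scaleFactor)
  }
}

## ---- internal input handling ----

.getCounts <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
}

.getCellMeta <- function(x) {
  if (!is(x, "SummarizedExperiment"))
    stop("supply 'subject' and 'cellType' when not using a SingleCellExperiment")
  cd <- as.data.frame(colData(x))
  if (!all(c("subject", "cell_type") %in% colnames(cd)))
    stop("colData must contain 'subject' and 'cell_type'")
  data.frame(subject = as.character(cd$subject),
             cell_type = as.character(cd$cell_type))
}

.designFromColData <- function(sce, factorName) {
  cd <- as.data.frame(colData(sce))
  if (!all(c("subject", "group") %in% colnames(cd)))
    stop("supply 'design' or colData columns 'subject' and 'group'")
  u <- unique(cd[, c("subject", "group")])
  if (anyDuplicated(u$subject))
    stop("subjects with inconsistent group labels")
  design <- data.frame(A = as.numeric(u$group), row.names = u$subject)
  if (!identical(factorName, "A"))
    stop("derived designs use factor name 'A'")
  design
}

.checkDesign <- function(design, factorName, covariateNames) {
  if (is.null(rownames(design))) stop("design must have subject row names")
  cols <- c(factorName, covariateNames)
  if (!all(cols %in% colnames(design)))
    stop("design lacks columns: ",
         paste(setdiff(cols, colnames(design)), collapse = ", "))
  if (anyNA(design[, cols])) stop("design contains missing values")
  for (f in factorName) {
    v <- design[[f]]
    if (!is.numeric(v)) stop(sprintf("tested factor '%s' must be numeric", f))
    if (length(unique(v)) < 2) stop(sprintf("tested factor '%s' is constant", f))
  }
  invisible(TRUE)
}
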