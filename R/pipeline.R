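#' Run the full tree-guided DE pipeline
#'
#' Executes the complete analysis on a single-cell count dataset:
#' low-expression gene filtering, pseudo-bulk aggregation and
#' log-normalization, per-cell-type DE screening, cell-type tree
#' construction (or validation of a user tree), prior estimation on the
#' tree, per-gene model fitting, exact posterior computation and DE
#' calling. The run is deterministic given its inputs.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a
#'   `counts` assay and colData `subject`, `cell_type`, or a bare count
#'   matrix plus `subject`/`cellType` vectors.
#' @param design per-subject data.frame (row names = subjects); taken from
#'   `metadata(sce)$design` or derived from a `group` colData column when
#'   `NULL`.
#' @param tree optional user-supplied [CellTypeTree-class] or newick
#'   string/path; when `NULL` the tree is estimated from the screen.
#' @param factorName,covariateNames design columns (see
#'   [aggregateCounts()]).
#' @param screenMethod backend for [screenDE()].
#' @param minCells low-expression filter (see [filterLowExpression()]).
#' @param scaleFactor log-normalization scale (see [logNormalize()]).
#' @param tstatThreshold informative-gene cutoff for tree construction.
#' @param pvalThreshold significance cutoff for prior estimation.
#' @param linkage clustering linkage for [buildTree()].
#' @param cutoff posterior DE call cutoff.
#' @param kMax enumeration guard for [computePosteriors()].
#' @param outputDir optional directory; when given, all intermediate
#'   tables (pseudo-bulk, screen, priors, posteriors, calls) and a JSON
#'   run manifest are written there.
#' @param subject,cellType per-cell labels when `sce` is a bare matrix.
#'
#' @return a list of class `treeDEResult` with elements `pb`, `screen`,
#'   `tree`, `fits`, `posterior`, `calls` and `manifest`.
#' @export
runPipeline <- function(sce, design = NULL, tree = NULL,
                        factorName = "A", covariateNames = character(0),
                        screenMethod = c("nb_wald", "ols_t"),
                        minCells = 10, scaleFactor = 1e4,
                        tstatThreshold = 2.58, pvalThreshold = 0.01,
                        linkage = "average", cutoff = 0.95, kMax = 16,
                        outputDir = NULL, subject = NULL, cellType = NULL) {
  screenMethod <- match.arg(screenMethod)
  if (is.null(design) && is(sce, "SummarizedExperiment")) {
    design <- if (!is.null(metadata(sce)$design)) metadata(sce)$design
              else .designFromColData(sce, factorName)
  }
  if (is.null(design)) stop("a per-subject design table is required")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  counts <- .getCounts(sce)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  ct <- if (is.null(cellType)) .getCellMeta(sce)$cell_type else as.character(cellType)
  filt <- stage("filter", filterLowExpression(counts, minCells = minCells, cellType = ct))
  keep <- rownames(counts) %in% filt$universe
  countsUse <- counts[keep, , drop = FALSE]

  pb <- stage("aggregate", aggregateCounts(
    countsUse, design = design, factorName = factorName,
    covariateNames = covariateNames,
    subject = if (is.null(subject)) .getCellMeta(sce)$subject else subject,
    cellType = ct))
  pb <- stage("normalize", logNormalize(pb, scaleFactor = scaleFactor))

  screen <- stage("screen", screenDE(pb, method = screenMethod))

  userTree <- !is.null(tree)
  if (userTree) {
    if (is.character(tree))
      tree <- stage("tree", readCellTypeTree(tree, cellTypes = cellTypes(pb)))
    if (!setequal(leafLabels(tree), cellTypes(pb)))
      stop("user tree leaves do not match the data's cell types")
  } else {
    tree <- stage("tree", buildTree(
      computeDistanceMatrix(screen, selectInformativeGenes(screen, tstatThreshold)),
      linkage = linkage))
  }
  tree <- stage("priors", estimatePriors(tree, screen, pvalThreshold = pvalThreshold))

  fits <- stage("fit", fitGeneModels(pb))
  posterior <- stage("posterior", computePosteriors(fits, tree, kMax = kMax))
  calls <- stage("call", callDEGenes(posterior, cutoff = cutoff))

  manifest <- list(
    package = "treeDE",
    version = as.character(packageVersion("treeDE")),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    tree = if (userTree) "user" else "estimated",
    config = list(factorName = factorName, covariateNames = covariateNames,
                  screenMethod = screenMethod, minCells = minCells,
                  scaleFactor = scaleFactor, tstatThreshold = tstatThreshold,
                  pvalThreshold = pvalThreshold, linkage = linkage,
                  cutoff = cutoff, kMax = kMax),
    nGenesUniverse = length(filt$universe),
    cellTypes = cellTypes(pb),
    nSubjects = nrow(pb@design)
  )

  res <- structure(list(pb = pb, screen = screen, tree = tree, fits = fits,
                        posterior = posterior, calls = calls,
                        manifest = manifest),
                   class = "treeDEResult")
  if (!is.null(outputDir)) .writeRunOutputs(res, outputDir)
  res
}

#' @export
print.treeDEResult <- function(x, ...) {
  cat("treeDE pipeline result\n")
  cat("  genes:", length(geneIds(x$posterior)),
      " cell types:", paste(cellTypes(x$posterior), collapse = ", "), "\n")
  cat("  tree:", x$manifest$tree, "\n")
  ncalled <- vapply(x$calls, function(d) sum(d$called), integer(1))
  cat("  DE calls per type:",
      paste(sprintf("%s=%d", names(ncalled), ncalled), collapse = ", "), "\n")
  invisible(x)
}

.writeRunOutputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = TRUE)
  for (k in cellTypes(res$pb)) {
    wt(rawCounts(res$pb, k), sprintf("pseudobulk_raw_%s.tsv", k))
    wt(normExpr(res$pb, k), sprintf("pseudobulk_norm_%s.tsv", k))
    scr <- data.frame(gene = geneIds(res$screen),
                      tstat = res$screen@tstat[, k],
                      pval = res$screen@pval[, k])
    write.table(scr, file.path(dir, sprintf("screen_%s.tsv", k)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$calls[[k]], file.path(dir, sprintf("calls_%s.tsv", k)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(posteriorProb(res$posterior), "posterior.tsv")
  write.table(priorTable(res$tree), file.path(dir, "tree_priors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeCellTypeTree(res$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
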