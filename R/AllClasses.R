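#' Per-cell-type pseudo-bulk expression set
#'
#' Container for the per-cell-type pseudo-bulk matrices produced by
#' [aggregateCounts()]. For each cell type `k` it holds a genes x subjects
#' matrix of raw count sums (`raw`) and, after [logNormalize()], the
#' log-normalized values (`norm`) the downstream Gaussian model operates on.
#' Subjects missing from a cell type (zero cells for that subject/type pair)
#' are dropped from that type's matrix only and recorded in `missingPairs`.
#'
#' @slot raw named list of K genes x subjects matrices of summed counts.
#' @slot norm named list with the same shapes, log-normalized; empty until
#'   [logNormalize()] is called.
#' @slot subjects named list of per-type subject vectors (column names of
#'   the matrices).
#' @slot design data.frame of per-subject variables, row names are subject
#'   identifiers covering every subject in any cell type.
#' @slot factorName name(s) of the tested column(s) of `design`.
#' @slot covariateNames names of adjustment covariate columns (may be empty).
#' @slot geneIds character vector of gene identifiers (row names).
#' @slot missingPairs data.frame with columns `subject`, `cell_type` listing
#'   subject/type pairs with zero cells.
#'
#' @aliases PseudoBulkSet-class
#' @exportClass PseudoBulkSet
setClass("PseudoBulkSet",
  representation(
    raw = "list",
    norm = "list",
    subjects = "list",
    design = "data.frame",
    factorName = "character",
    covariateNames = "character",
    geneIds = "character",
    missingPairs = "data.frame"
  ),
  prototype(
    norm = list(),
    covariateNames = character(0),
    missingPairs = data.frame(subject = character(0), cell_type = character(0))
  )
)

setValidity("PseudoBulkSet", function(object) {
  msg <- character(0)
  types <- names(object@raw)
  if (is.null(types) || any(types == ""))
    msg <- c(msg, "'raw' must be a named list of matrices (one per cell type)")
  for (k in types) {
    m <- object@raw[[k]]
    if (!is.matrix(m) || nrow(m) != length(object@geneIds))
      msg <- c(msg, sprintf("raw[['%s']] must be a matrix with one row per gene", k))
    else {
      if (any(m < 0)) msg <- c(msg, sprintf("raw[['%s']] has negative entries", k))
      if (!identical(colnames(m), object@subjects[[k]]))
        msg <- c(msg, sprintf("colnames(raw[['%s']]) must equal subjects[['%s']]", k, k))
      if (!all(object@subjects[[k]] %in% rownames(object@design)))
        msg <- c(msg, sprintf("subjects of '%s' missing from design", k))
    }
  }
  if (length(object@norm)) {
    if (!identical(names(object@norm), types))
      msg <- c(msg, "'norm' must have the same cell types as 'raw'")
    for (k in names(object@norm)) {
      if (!identical(dim(object@norm[[k]]), dim(object@raw[[k]])))
        msg <- c(msg, sprintf("norm[['%s']] shape differs from raw", k))
      else if (any(!is.finite(object@norm[[k]])))
        msg <- c(msg, sprintf("norm[['%s']] has non-finite values", k))
    }
  }
  if (!all(object@factorName %in% colnames(object@design)))
    msg <- c(msg, "factorName not found in design columns")
  if (!all(object@covariateNames %in% colnames(object@design)))
    msg <- c(msg, "covariateNames not found in design columns")
  if (length(msg)) msg else TRUE
})

#' First-pass per-cell-type DE screen results
#'
#' Genes x cell types matrices of signed test statistics and two-sided
#' p-values from [screenDE()]. Used to build the cell-type tree and to
#' estimate the DE-state priors. Entries are `NA` where a fit failed or a
#' cell type's design was degenerate.
#'
#' @slot tstat genes x cell types matrix of signed statistics.
#' @slot pval matching matrix of two-sided p-values in \[0, 1\].
#' @slot method screening backend label ("nb_wald" or "ols_t").
#'
#' @aliases ScreenResult-class
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(tstat = "matrix", pval = "matrix", method = "character")
)

setValidity("ScreenResult", function(object) {
  msg <- character(0)
  if (!identical(dim(object@tstat), dim(object@pval)))
    msg <- c(msg, "tstat and pval must have identical dimensions")
  if (!identical(dimnames(object@tstat), dimnames(object@pval)))
    msg <- c(msg, "tstat and pval must have identical dimnames")
  pv <- object@pval
  if (any(pv < 0 | pv > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (any(is.infinite(object@tstat), na.rm = TRUE))
    msg <- c(msg, "tstat must be finite where defined")
  if (length(msg)) msg else TRUE
})

#' Cell-type hierarchy with DE-state prior parameters
#'
#' A rooted tree (binary or multifurcating) whose leaves are cell types.
#' Each node carries the set of descendant cell types, a marginal prior
#' probability `pi` of being in the DE state, and (except the root) a
#' conditional inheritance probability `p` of being DE given its parent is
#' DE; a node whose parent is non-DE is non-DE with probability one.
#'
#' @slot phylo the underlying `ape::phylo` object (branch lengths unused).
#' @slot nodes data.frame with one row per node: `id` (leaves first,
#'   1..K in tip-label order), `parent` (NA for the root), `label`,
#'   `leaf` (logical), `pi`, `p` (NA until priors are set; root `p` is NA).
#' @slot members list of integer vectors: descendant leaf ids per node.
#'
#' @aliases CellTypeTree-class
#' @exportClass CellTypeTree
setClass("CellTypeTree",
  representation(phylo = "ANY", nodes = "data.frame", members = "list")
)

setValidity("CellTypeTree", function(object) {
  msg <- character(0)
  nd <- object@nodes
  need <- c("id", "parent", "label", "leaf", "pi", "p")
  if (!all(need %in% colnames(nd)))
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  K <- sum(nd$leaf)
  root <- which(is.na(nd$parent))
  if (length(root) != 1L) msg <- c(msg, "tree must have exactly one root")
  else {
    if (length(object@members[[root]]) != K)
      msg <- c(msg, "root members must contain all leaves")
    # disjoint-union: each node's member set is the disjoint union of its children's
    for (n in nd$id[!nd$leaf]) {
      ch <- nd$id[!is.na(nd$parent) & nd$parent == n]
      un <- sort(unlist(object@members[ch]))
      if (any(duplicated(un)) || !identical(un, sort(object@members[[n]])))
        msg <- c(msg, sprintf("members of node %d are not the disjoint union of its children", n))
    }
  }
  if (any(duplicated(nd$label[nd$leaf])))
    msg <- c(msg, "duplicated leaf labels")
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok(nd$pi)) msg <- c(msg, "pi values must lie in [0, 1]")
  if (!ok(nd$p)) msg <- c(msg, "p values must lie in [0, 1]")
  # monotone nesting of marginals along each edge
  if (all(!is.na(nd$pi))) {
    for (n in nd$id[!is.na(nd$parent)])
      if (nd$pi[n] > nd$pi[nd$parent[n]] + 1e-12) {
        msg <- c(msg, "child pi exceeds parent pi")
        break
      }
  }
  if (length(msg)) msg else TRUE
})

#' Posterior DE probabilities from exact configuration enumeration
#'
#' Result of [computePosteriors()]: per-gene, per-cell-type posterior
#' probabilities of the DE state, the per-gene log marginal likelihood, and
#' the fitted effect sizes carried over from [fitGeneModels()].
#'
#' @slot posterior genes x cell types matrix of P(Z = 1 | data).
#' @slot logMarginal per-gene log marginal likelihood log P(Y).
#' @slot delta genes x cell types matrix of fitted effects (alternative
#'   model coefficient of the tested factor).
#' @slot tree the [CellTypeTree-class] (priors filled) used for inference.
#'
#' @aliases DEPosterior-class
#' @exportClass DEPosterior
setClass("DEPosterior",
  representation(posterior = "matrix", logMarginal = "numeric",
                 delta = "matrix", tree = "CellTypeTree")
)

setValidity("DEPosterior", function(object) {
  msg <- character(0)
  if (any(object@posterior < -1e-10 | object@posterior > 1 + 1e-10, na.rm = TRUE))
    msg <- c(msg, "posterior probabilities must lie in [0, 1]")
  if (nrow(object@posterior) != length(object@logMarginal))
    msg <- c(msg, "logMarginal length must match number of genes")
  if (!identical(dim(object@posterior), dim(object@delta)))
    msg <- c(msg, "posterior and delta must have identical dimensions")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PseudoBulkSet", function(object) {
  cat("PseudoBulkSet with", length(object@geneIds), "genes,",
      length(object@raw), "cell types,",
      nrow(object@design), "subjects\n")
  cat("  cell types:", paste(names(object@raw), collapse = ", "), "\n")
  cat("  normalized:", if (length(object@norm)) "yes" else "no", "\n")
  if (nrow(object@missingPairs))
    cat("  missing (subject, type) pairs:", nrow(object@missingPairs), "\n")
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult (", object@method, "): ", nrow(object@tstat), " genes x ",
      ncol(object@tstat), " cell types; ", sum(is.na(object@tstat)),
      " missing statistics\n", sep = "")
})

setMethod("show", "CellTypeTree", function(object) {
  K <- sum(object@nodes$leaf)
  cat("CellTypeTree with", K, "leaves:",
      paste(object@nodes$label[object@nodes$leaf], collapse = ", "), "\n")
  cat("  priors:", if (all(is.na(object@nodes$pi))) "unset" else "set", "\n")
})

setMethod("show", "DEPosterior", function(object) {
  cat("DEPosterior:", nrow(object@posterior), "genes x",
      ncol(object@posterior), "cell types\n")
})
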