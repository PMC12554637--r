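#' Accessors for treeDE classes
#'
#' @param x a treeDE object.
#' @param type a cell-type label.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("rawCounts", function(x, type) standardGeneric("rawCounts"))

#' @rdname accessors
#' @export
setGeneric("normExpr", function(x, type) standardGeneric("normExpr"))

#' @rdname accessors
#' @export
setGeneric("screenStats", function(x) standardGeneric("screenStats"))

#' @rdname accessors
#' @export
setGeneric("screenPvals", function(x) standardGeneric("screenPvals"))

#' @rdname accessors
#' @export
setGeneric("posteriorProb", function(x) standardGeneric("posteriorProb"))

#' @rdname accessors
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))

#' @rdname accessors
#' @export
setGeneric("priorTable", function(x) standardGeneric("priorTable"))

#' @rdname accessors
setMethod("cellTypes", "PseudoBulkSet", function(x) names(x@raw))

#' @rdname accessors
setMethod("cellTypes", "ScreenResult", function(x) colnames(x@tstat))

#' @rdname accessors
setMethod("cellTypes", "DEPosterior", function(x) colnames(x@posterior))

#' @rdname accessors
setMethod("geneIds", "PseudoBulkSet", function(x) x@geneIds)

#' @rdname accessors
setMethod("geneIds", "ScreenResult", function(x) rownames(x@tstat))

#' @rdname accessors
setMethod("geneIds", "DEPosterior", function(x) rownames(x@posterior))

#' @rdname accessors
setMethod("rawCounts", "PseudoBulkSet", function(x, type) {
  if (missing(type)) return(x@raw)
  x@raw[[match.arg(type, names(x@raw))]]
})

#' @rdname accessors
setMethod("normExpr", "PseudoBulkSet", function(x, type) {
  if (!length(x@norm)) stop("pseudo-bulk set is not normalized; run logNormalize()")
  if (missing(type)) return(x@norm)
  x@norm[[match.arg(type, names(x@norm))]]
})

#' @rdname accessors
setMethod("screenStats", "ScreenResult", function(x) x@tstat)

#' @rdname accessors
setMethod("screenPvals", "ScreenResult", function(x) x@pval)

#' @rdname accessors
setMethod("posteriorProb", "DEPosterior", function(x) x@posterior)

#' @rdname accessors
setMethod("leafLabels", "CellTypeTree", function(x) {
  x@nodes$label[x@nodes$leaf]
})

#' @rdname accessors
setMethod("priorTable", "CellTypeTree", function(x) {
  nd <- x@nodes
  data.frame(
    node = nd$id,
    label = nd$label,
    members = vapply(x@members, function(m)
      paste(nd$label[m], collapse = ","), character(1)),
    leaf = nd$leaf,
    pi = nd$pi,
    p = nd$p,
    stringsAsFactors = FALSE
  )
})
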